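#' Read dose-response grids for the sparse 1x5 combination design
#'
#' Long-format TSV with columns `cell_line`, `primary_drug`,
#' `rescuer_inhibitor`, `condition` in \{untreated, primary, single,
#' combo\}, `dose_index` (1-5 for single/combo, NA otherwise), `replicate`,
#' `cell_count`. One grid = one (cell line, rescuer inhibitor) block.
#'
#' @param path file path or data frame.
#' @return Tibble of dose-response measurements.
#' @export
read_dose_grids <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  need <- c("cell_line", "primary_drug", "rescuer_inhibitor", "condition",
            "dose_index", "replicate", "cell_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dose grid missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$cell_count < 0)) stop("cell counts must be >= 0")
  tibble::as_tibble(df)
}

#' Bliss-independence synergism at one dose point
#'
#' `Ratio(X) = count(primary + R at dose c) / count(primary alone)` and
#' `Ratio(Y) = count(R alone at dose c) / count(untreated)`;
#' `Synergism = Ratio(Y) / Ratio(X)`. Under Bliss independence the combined
#' surviving fraction is the product of single-agent fractions, making the
#' value 1; values above 1 indicate the combination kills more than
#' expected (synergy). A zero combination count would give an infinite
#' ratio and is capped at `cap` with a flag.
#'
#' @param count_untreated,count_primary reference counts (means over their
#'   replicates); both must be > 0.
#' @param count_single,count_combo counts for R alone and primary+R at one
#'   dose-replicate point.
#' @param cap cap for degenerate (zero-combo) points, default 100.
#' @return One-row tibble with `ratio_x`, `ratio_y`, `synergism`, `capped`.
#' @export
bliss_point <- function(count_untreated, count_primary, count_single,
                        count_combo, cap = 100) {
  if (count_untreated <= 0 || count_primary <= 0) {
    stop("untreated and primary-alone counts must be > 0")
  }
  ratio_y <- count_single / count_untreated
  ratio_x <- count_combo / count_primary
  capped <- ratio_x == 0
  syn <- if (capped) cap else ratio_y / ratio_x
  tibble::tibble(ratio_x = ratio_x, ratio_y = ratio_y,
                 synergism = min(syn, cap), capped = capped || syn > cap)
}

grid_points <- function(grid, cap = 100) {
  untreated <- mean(grid$cell_count[grid$condition == "untreated"])
  primary <- mean(grid$cell_count[grid$condition == "primary"])
  singles <- grid[grid$condition == "single", ]
  combos <- grid[grid$condition == "combo", ]
  pts <- dplyr::inner_join(
    dplyr::select(singles, "dose_index", "replicate", single = "cell_count"),
    dplyr::select(combos, "dose_index", "replicate", combo = "cell_count"),
    by = c("dose_index", "replicate"))
  purrr::pmap_dfr(pts, function(dose_index, replicate, single, combo) {
    dplyr::bind_cols(tibble::tibble(dose_index = dose_index,
                                    replicate = replicate),
                     bliss_point(untreated, primary, single, combo,
                                 cap = cap))
  })
}

#' Call synergy/antagonism for a screen of dose grids
#'
#' For each (cell line, rescuer inhibitor) grid, computes the Bliss
#' synergism of its (up to) 10 dose-replicate points, takes the median as
#' the grid's synergism, and tests `Ratio(Y)` against `Ratio(X)` with a
#' Wilcoxon rank-sum test. P-values are Benjamini-Hochberg corrected across
#' all grids in the screen; a grid is called `synergistic` when median
#' synergism > 1.25 and q < 0.05, `antagonistic` when < 0.75 and q < 0.05,
#' otherwise `neither`. Grids with fewer than `min_points` valid points are
#' called `neither` with `quality = "insufficient_points"`.
#'
#' @param grids long-format tibble from [read_dose_grids()] covering one or
#'   more grids.
#' @param fdr threshold (default 0.05).
#' @param min_points minimum valid dose points (default 6).
#' @param cap degenerate-point cap (see [bliss_point()]).
#' @return Tibble: per grid, `synergism` (median), `p`, `q`, `call`,
#'   `n_points`, `quality`.
#' @export
synergy_call <- function(grids, fdr = 0.05, min_points = 6L, cap = 100) {
  grids <- tibble::as_tibble(grids)
  res <- grids |>
    dplyr::group_by(.data$cell_line, .data$rescuer_inhibitor) |>
    dplyr::group_modify(function(g, key) {
      pts <- grid_points(g, cap = cap)
      pts <- pts[is.finite(pts$synergism), ]
      if (nrow(pts) < min_points) {
        return(tibble::tibble(synergism = NA_real_, p = NA_real_,
                              n_points = nrow(pts),
                              quality = "insufficient_points"))
      }
      wt <- suppressWarnings(stats::wilcox.test(pts$ratio_y, pts$ratio_x))
      tibble::tibble(synergism = stats::median(pts$synergism),
                     p = wt$p.value, n_points = nrow(pts), quality = "ok")
    }) |>
    dplyr::ungroup()
  res$q <- bh_fdr(res$p)
  res$call <- dplyr::case_when(
    res$quality != "ok" ~ "neither",
    res$synergism > 1.25 & res$q < fdr ~ "synergistic",
    res$synergism < 0.75 & res$q < fdr ~ "antagonistic",
    TRUE ~ "neither")
  res
}
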