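# Local RNG scope: save the caller's .Random.seed, set a fresh seed, and
# let the caller restore on exit, so seeded internals never disturb the
# session stream.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom survival coxph Surv strata
NULL

#' @export
generics::tidy

#' @export
generics::glance
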