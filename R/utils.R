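# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a local RNG seed
#'
#' Seeds the RNG, evaluates `code`, and restores the caller's RNG state
#' afterwards.  The simulation operations ([simulate_visit_schedule()]
#' and friends) draw from the current RNG stream; wrap them in
#' `with_seed()` for reproducibility without disturbing the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_sogrisk <- function(..., class = "sogrisk_error") {
  stop(errorCondition(paste0(...), class = c(class, "sogrisk_error")))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_sogrisk(name, " must be a probability in [0, 1]",
                 class = "sogrisk_config_error")
}

assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok)
    stop_sogrisk(name, if (strict) " must be > 0" else " must be >= 0",
                 class = "sogrisk_config_error")
}

# days per month used for all date -> month conversions
DAYS_PER_MONTH <- 365.25 / 12

# cause codes used throughout
CAUSE_CENSORED <- 0L
CAUSE_PROGRESSION <- 1L
CAUSE_DEATH <- 2L

cause_from_label <- function(x) {
  lab <- tolower(as.character(x))
  code <- match(lab, c("censored", "progression", "death")) - 1L
  if (anyNA(code))
    stop_sogrisk("unknown outcome cause label(s): ",
                 paste(unique(lab[is.na(code)]), collapse = ", "),
                 class = "sogrisk_data_error")
  code
}

cause_to_label <- function(code) {
  c("censored", "progression", "death")[code + 1L]
}
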