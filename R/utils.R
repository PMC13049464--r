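#' @keywords internal
"_PACKAGE"

# Condition helper: all package errors/warnings carry a "thermotraits_<class>"
# condition class so callers can branch on failure mode.
tt_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ...,
                      class = c(paste0("thermotraits_", class), "thermotraits_error"),
                      call = call))
}

tt_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ...,
                           class = c(paste0("thermotraits_", class), "thermotraits_warning")))
}

#' Mix a base seed with a string label
#'
#' Derives a reproducible 31-bit integer seed from a base seed and a label,
#' so that different plots (or processes) generated from the same run seed
#' receive distinct but deterministic random streams.
#'
#' @param seed integer base seed.
#' @param label character scalar mixed into the seed.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
mix_seed <- function(seed, label = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

# Inclusive membership of dates in a [start, end] interval.
date_in <- function(dates, interval) {
  dates >= interval[1] & dates <= interval[2]
}

processes <- function() c("bacterial_growth", "fungal_growth", "respiration")

is_growth_process <- function(process) {
  process %in% c("bacterial_growth", "fungal_growth")
}

check_process <- function(process) {
  if (!process %in% processes()) {
    tt_stop("bad_process",
            sprintf("unknown process '%s'; expected one of %s",
                    process, paste(processes(), collapse = ", ")))
  }
  process
}
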