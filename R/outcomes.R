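#' Two-group risk mapping
#'
#' Collapses the four-class risk stratification into the two analysis
#' groups: group 1 = low + favorable-intermediate risk, group 2 =
#' unfavorable-intermediate + high risk.
#'
#' @param risk_class Character vector with values among `"low"`,
#'   `"favorable-IR"`, `"unfavorable-IR"`, `"high"`.
#' @return Integer vector of group codes (1 or 2), same length.
#' @examples
#' map_risk_group(rep(c("low", "favorable-IR", "unfavorable-IR", "high"),
#'                    c(6, 26, 31, 65)))
#' @export
map_risk_group <- function(risk_class) {
  if (length(risk_class) == 0) return(integer(0))
  map <- c(low = 1L, `favorable-IR` = 1L, `unfavorable-IR` = 2L, high = 2L)
  unknown <- setdiff(unique(risk_class), names(map))
  if (length(unknown))
    stop("unknown risk class(es): ", paste(unknown, collapse = ", "))
  unname(map[risk_class])
}

#' Biochemical recurrence under the PHOENIX rule
#'
#' Declares biochemical recurrence (BCR) at the first time the PSA rises by
#' at least 2 ng/mL above the running nadir (the minimum of all preceding
#' values, including the current candidate's predecessors), within the
#' horizon. The comparison is inclusive: a rise of exactly 2.0 qualifies.
#' Measurements after the first qualifying rise cannot change the outcome.
#'
#' @param psa_series Data frame with columns `time` (years from treatment)
#'   and `psa` (ng/mL), at least 2 rows.
#' @param horizon Follow-up horizon in years (default 10).
#' @return `"yes"` or `"no"`.
#' @examples
#' derive_bcr(data.frame(time = c(0, 1, 2, 3), psa = c(4.0, 0.5, 0.4, 2.5)))
#' @export
derive_bcr <- function(psa_series, horizon = 10) {
  stopifnot(is.data.frame(psa_series),
            all(c("time", "psa") %in% names(psa_series)))
  s <- psa_series[order(psa_series$time), ]
  if (nrow(s) < 2) stop("PSA series needs at least 2 measurements")
  in_h <- s$time <= horizon
  psa <- s$psa[in_h]
  if (length(psa) < 2) return("no")
  nadir <- cummin(c(Inf, psa[-length(psa)]))
  if (any(psa >= nadir + 2)) "yes" else "no"
}
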