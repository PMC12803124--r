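# Discrete hemodynamic loading cases: LOW / NORMAL / HIGH end-diastolic and
# end-systolic pressure levels. RV end-diastolic pressure follows the LV at
# a 4:9 ratio (rounded to 3 decimals); end-systolic RV pressures use the
# tabulated levels directly.

LVEDP_LEVELS <- c(LOW = 0.80, NORMAL = 1.20, HIGH = 1.60)   # kPa
LVESP_LEVELS <- c(LOW = 14.0, NORMAL = 18.0, HIGH = 25.0)   # kPa
RVESP_LEVELS <- c(LOW = 2.0, NORMAL = 3.0, HIGH = 4.0)      # kPa

#' Construct a hemodynamic loading case
#'
#' @param level_ed,level_es `"LOW"`, `"NORMAL"` or `"HIGH"`.
#' @return an object of class `hemodynamic_case` with fields `lvedp`,
#'   `rvedp`, `lvesp`, `rvesp` (kPa) and the level labels.
#' @export
make_hemodynamic_case <- function(level_ed, level_es) {
  level_ed <- toupper(level_ed); level_es <- toupper(level_es)
  if (!level_ed %in% names(LVEDP_LEVELS))
    stop_invariant(sprintf("unknown ED pressure level '%s'", level_ed))
  if (!level_es %in% names(LVESP_LEVELS))
    stop_invariant(sprintf("unknown ES pressure level '%s'", level_es))
  lvedp <- LVEDP_LEVELS[[level_ed]]
  case <- structure(list(
    lvedp = lvedp,
    rvedp = round(4 / 9 * lvedp, 3),
    lvesp = LVESP_LEVELS[[level_es]],
    rvesp = RVESP_LEVELS[[level_es]],
    level_ed = level_ed, level_es = level_es,
    ta_max = 200.0), class = "hemodynamic_case")
  stopifnot(case$lvesp > case$lvedp, case$rvesp > case$rvedp)
  case
}

#' @export
print.hemodynamic_case <- function(x, ...) {
  cat(sprintf("hemodynamic_case %s/%s: LVEDP %.2f, RVEDP %.3f, LVESP %.1f, RVESP %.1f kPa\n",
              x$level_ed, x$level_es, x$lvedp, x$rvedp, x$lvesp, x$rvesp))
  invisible(x)
}

#' All nine ED x ES level combinations
#' @return list of nine `hemodynamic_case` objects.
#' @export
hemodynamic_grid <- function() {
  out <- list()
  for (ed in names(LVEDP_LEVELS))
    for (es in names(LVESP_LEVELS))
      out[[paste(ed, es, sep = "/")]] <- make_hemodynamic_case(ed, es)
  out
}
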