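# Specimen-level porosity characterization and comparative reporting.

#' Summarize per-pore volumes into a porosity report
#'
#' Computes the standard specimen-level porosity characteristics: mean pore
#' volume `m_V`, standard deviation of pore volume `Delta_V` (population form:
#' the numbers describe the observed set of pores, not an inference about a
#' larger population), and the total pore density `rho = V_sigma / V`, which
#' varies between 0 and 1.
#'
#' @param volumes numeric vector of per-pore volumes (pix^3); may be empty, in
#'   which case `m_V` and `Delta_V` are reported absent but `rho` is still
#'   computed.
#' @param V_sigma total pore volume; defaults to `sum(volumes)`.
#' @param V reference specimen volume; positive.
#' @param method which estimator produced the volumes: `"chords"`, `"depth"`
#'   or `"anisotropic"`.
#' @param scale micrometres per pixel (for the metric columns).
#' @param settings named list snapshot of the estimator settings; reports are
#'   mutually comparable only when their snapshots agree (see
#'   [compare_reports()]).
#' @param specimen_id identifier for the specimen/image.
#' @return A list of class `porosity_report` with `specimen_id`, `method`,
#'   `n_pores`, `m_V`, `Delta_V`, `m_V_um3`, `Delta_V_um3`, `rho`, `V_sigma`,
#'   `V`, `settings`.
#' @examples
#' summarize_porosity(c(50, 150), V = 1000)  # m_V = 100, Delta_V = 50, rho = 0.2
#' @export
summarize_porosity <- function(volumes, V_sigma = sum(volumes), V,
                               method = c("chords", "depth", "anisotropic"),
                               scale = 1, settings = list(),
                               specimen_id = NA_character_) {
  method <- match.arg(method)
  if (!is.numeric(V) || length(V) != 1L || V <= 0)
    stop("'V' must be a single positive reference volume")
  if (length(volumes)) {
    m_V <- mean(volumes)
    Delta_V <- sqrt(mean((volumes - m_V)^2))
  } else {
    m_V <- NA_real_
    Delta_V <- NA_real_
  }
  structure(list(
    specimen_id = specimen_id,
    method = method,
    n_pores = length(volumes),
    m_V = m_V, Delta_V = Delta_V,
    m_V_um3 = m_V * scale^3, Delta_V_um3 = Delta_V * scale^3,
    rho = V_sigma / V,
    V_sigma = V_sigma, V = V,
    settings = settings
  ), class = "porosity_report")
}

#' Build a porosity report from a volume estimate
#'
#' @param est a `volume_estimate` from [estimate_volumes()].
#' @param specimen_id identifier for the specimen/image.
#' @return A `porosity_report` (see [summarize_porosity()]).
#' @export
report_from_estimate <- function(est, specimen_id = NA_character_) {
  stopifnot(inherits(est, "volume_estimate"))
  summarize_porosity(est$per_pore$volume_pix3, V_sigma = est$V_sigma,
                     V = est$V_ref, method = "chords",
                     scale = est$settings$scale %||% 1,
                     settings = est$settings, specimen_id = specimen_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.porosity_report <- function(x, ...) {
  cat(sprintf("porosity_report [%s], specimen %s: %d pore(s)\n",
              x$method, x$specimen_id, x$n_pores))
  cat(sprintf("  m_V = %.4g, Delta_V = %.4g (pix^3); rho = %.4g\n",
              x$m_V, x$Delta_V, x$rho))
  invisible(x)
}

#' Side-by-side comparison of porosity reports
#'
#' Porosity parameters evaluated in different specimens are mutually
#' comparable only when obtained under identical analysis settings; the
#' comparison therefore refuses report sets whose settings snapshots differ,
#' naming the mismatched keys.
#'
#' @param reports a list of `porosity_report` objects (at least 2).
#' @return Data frame with one row per specimen: `specimen_id`, `method`,
#'   `n_pores`, `m_V`, `Delta_V`, `rho`.
#' @export
compare_reports <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports to compare")
  ok <- vapply(reports, inherits, logical(1), "porosity_report")
  if (!all(ok)) stop("all elements must be porosity_report objects")
  ref <- reports[[1]]$settings
  mismatched <- character(0)
  for (i in seq_along(reports)[-1]) {
    s <- reports[[i]]$settings
    keys <- union(names(ref), names(s))
    for (k in keys) {
      if (!identical(ref[[k]], s[[k]])) mismatched <- c(mismatched, k)
    }
  }
  if (length(mismatched))
    stop("reports are not comparable: settings differ in ",
         paste(sort(unique(mismatched)), collapse = ", "))
  data.frame(
    specimen_id = vapply(reports, `[[`, character(1), "specimen_id"),
    method = vapply(reports, `[[`, character(1), "method"),
    n_pores = vapply(reports, `[[`, integer(1), "n_pores"),
    m_V = vapply(reports, `[[`, numeric(1), "m_V"),
    Delta_V = vapply(reports, `[[`, numeric(1), "Delta_V"),
    rho = vapply(reports, `[[`, numeric(1), "rho")
  )
}

#' Write a porosity report to JSON
#'
#' @param report a `porosity_report`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "porosity_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
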