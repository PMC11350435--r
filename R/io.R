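# CSV / JSON export contracts.  All floating point is written with 12
# significant digits so identical runs produce byte-identical files.

sig12 <- function(df) {
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], 12)
  df
}

#' Export continuation objects to CSV
#'
#' `write_branch_csv()` writes an equilibrium branch (parameter, state,
#' eigenvalues, test functions, stability); `write_locus_csv()` a
#' two-parameter curve; `write_sweep_csv()` a scenario sweep;
#' `write_heatmap_csv()` a heat map in long format (`p1`, `p2`, outputs,
#' oscillatory flag).
#'
#' @param x the object.
#' @param path output file.
#' @export
write_branch_csv <- function(x, path) {
  stopifnot(inherits(x, c("mk_branch", "mk_lcbranch")))
  utils::write.csv(sig12(x$points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_branch_csv
#' @export
write_locus_csv <- function(x, path) {
  stopifnot(inherits(x, "mk_twoparam"))
  utils::write.csv(sig12(x$points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_branch_csv
#' @export
write_sweep_csv <- function(x, path) {
  df <- if (inherits(x, "mk_sweep")) x$results else x
  utils::write.csv(sig12(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_branch_csv
#' @export
write_heatmap_csv <- function(x, path) {
  stopifnot(inherits(x, "mk_heatmap"))
  long <- expand.grid(p1 = x$grid1, p2 = x$grid2)
  long$mean_glut <- as.vector(x$mean_glut)
  long$mean_gaba <- as.vector(x$mean_gaba)
  long$mean_mepd <- as.vector(x$mean_mepd)
  long$oscillatory <- as.vector(x$oscillatory)
  names(long)[1:2] <- x$pair
  utils::write.csv(sig12(long), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export bifurcation points to JSON
#'
#' @param points a list of `mk_bifpoint` objects (or a single one).
#' @param path output file.
#' @export
write_points_json <- function(points, path) {
  if (inherits(points, "mk_bifpoint")) points <- list(points)
  lst <- lapply(points, function(b) {
    o <- list(kind = b$kind, param = b$param, value = signif(b$value, 12),
              state = as.list(signif(b$state, 12)),
              eigenvalues_re = signif(Re(b$eigenvalues), 12),
              eigenvalues_im = signif(Im(b$eigenvalues), 12))
    if (!is.null(b$param2)) { o$param2 <- b$param2; o$value2 <- signif(b$value2, 12) }
    if (!is.null(b$omega)) o$omega <- signif(b$omega, 12)
    if (!is.null(b$diagnostics)) o$diagnostics <- b$diagnostics
    o
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export pulse statistics to JSON
#'
#' @param ps an `mk_pulse_stats` object.
#' @param path output file.
#' @export
write_pulses_json <- function(ps, path) {
  stopifnot(inherits(ps, "mk_pulse_stats"))
  jsonlite::write_json(
    list(classification = ps$classification, n_pulses = ps$n_pulses,
         mean_ipi = signif(ps$mean_ipi, 12), amplitude = signif(ps$amplitude, 12),
         peak_cv = signif(ps$peak_cv, 12),
         peak_times = signif(ps$peak_times, 12), ipis = signif(ps$ipis, 12)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
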