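# Plain-text readers/writers: angle scans and NITI parameters (CSV/JSON),
# fit results (JSON), wavefield and Stokes-volume containers (full-precision
# CSV matrix + JSON sidecar with grid metadata and seeds).

SCHEMA <- list(fit = "nitioce/fit/1", wavefield = "nitioce/wavefield/1",
               stokes = "nitioce/stokes-volume/1",
               manifest = "nitioce/subject-manifest/1")

read_numeric_col <- function(df, col, path) {
  if (!col %in% names(df))
    abort(sprintf("'%s' is missing required column '%s'", path, col),
          class = "nitioce_missing_column")
  x <- df[[col]]
  if (!is.numeric(x)) {
    xn <- suppressWarnings(as.numeric(x))
    if (any(is.na(xn) & !is.na(x)))
      abort(sprintf("non-numeric value in column '%s' of '%s'", col, path),
            class = "nitioce_non_numeric")
    x <- xn
  }
  x
}

#' Read / write an angle-resolved speed scan
#'
#' CSV with columns `angle_deg`, `speed_m_s`, and optionally `sd_m_s`.
#'
#' @param path File path.
#' @return `read_angle_scan`: a tibble.
#' @export
read_angle_scan <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  out <- tibble(angle_deg = read_numeric_col(df, "angle_deg", path),
                speed_m_s = read_numeric_col(df, "speed_m_s", path))
  if ("sd_m_s" %in% names(df))
    out$sd_m_s <- read_numeric_col(df, "sd_m_s", path)
  out
}

#' @param scan Data frame with scan columns.
#' @rdname read_angle_scan
#' @export
write_angle_scan <- function(scan, path) {
  check_angle_scan(scan)
  write_full_precision_csv(as.data.frame(scan), path)
  invisible(path)
}

write_full_precision_csv <- function(df, path) {
  fmt <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col),
    check.names = FALSE, optional = TRUE)
  names(fmt) <- names(df)
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Read / write NITI parameters as JSON
#'
#' Interface fields are in kPa: `mu_kPa`, `G_kPa`, `delta_kPa`, `rho_kg_m3`,
#' optional `lambda_over_mu` and `Q1_kPa`; stored internally in Pa.
#'
#' @param path File path.
#' @return `read_niti_params`: a [niti_params] object.
#' @export
read_niti_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mu_kPa", "G_kPa", "delta_kPa"))
    if (is.null(j[[f]]))
      abort(sprintf("'%s' is missing required field '%s'", path, f),
            class = "nitioce_missing_column")
  mu <- j$mu_kPa * 1e3
  niti_params(mu = mu, G = j$G_kPa * 1e3, delta = j$delta_kPa * 1e3,
              rho = if (is.null(j$rho_kg_m3)) 1000 else j$rho_kg_m3,
              lambda = if (is.null(j$lambda_over_mu)) NULL
                       else j$lambda_over_mu * mu,
              Q1 = if (is.null(j$Q1_kPa)) 0 else j$Q1_kPa * 1e3)
}

#' @param params A [niti_params] object.
#' @rdname read_niti_params
#' @export
write_niti_params <- function(params, path) {
  check_niti_params(params)
  jsonlite::write_json(
    list(mu_kPa = params$mu / 1e3, G_kPa = params$G / 1e3,
         delta_kPa = params$delta / 1e3, rho_kg_m3 = params$rho,
         lambda_over_mu = params$lambda / params$mu,
         Q1_kPa = params$Q1 / 1e3),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a fit result as JSON
#'
#' Versioned schema; parameters, derived ratios, convergence diagnostics and
#' LOO statistics survive the round trip exactly (full-precision numbers).
#'
#' @param fit A `niti_fit`.
#' @param path File path.
#' @return `read_fit_json`: a list mirroring the JSON (not a `niti_fit`).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "niti_fit"))
  payload <- list(
    schema = SCHEMA$fit,
    mu_Pa = fit$params$mu, G_Pa = fit$params$G, delta_Pa = fit$params$delta,
    alpha_deg = fit$alpha, rho_kg_m3 = fit$rho,
    rmse_m_s = fit$rmse,
    derived = list(G_over_mu = fit$params$G / fit$params$mu,
                   delta_over_mu = fit$params$delta / fit$params$mu,
                   EL_over_ET = with(engineering_moduli(fit$params), E_L / E_T)),
    convergence = fit$convergence[c("info", "niter", "deviance")],
    validity = fit$validity$constraint)
  if (!is.null(fit$loo))
    payload$loo <- list(n_folds = fit$loo$n_folds,
                        stats = fit$loo$stats, folds = fit$loo$folds)
  # I(17) significant digits so every double survives the text round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$schema) || j$schema != SCHEMA$fit)
    abort(sprintf("'%s' has schema '%s', expected '%s'", path,
                  j$schema %||% "<none>", SCHEMA$fit),
          class = "nitioce_schema")
  j
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a wavefield container
#'
#' Two files per field: `<stem>.csv` holding the velocity matrix (positions
#' by frames, full precision) and `<stem>.json` holding the uniform grid
#' (`dx`, `dt`, origins), seed, and generation metadata.
#'
#' @param wf A [wavefield].
#' @param stem Path stem (without extension).
#' @return `read_wavefield`: a [wavefield].
#' @export
write_wavefield <- function(wf, stem) {
  stopifnot(inherits(wf, "wavefield"))
  meta <- list(schema = SCHEMA$wavefield,
               n_x = length(wf$x), n_t = length(wf$t),
               dx = if (length(wf$x) > 1) diff(wf$x[1:2]) else 0,
               dt = diff(wf$t[1:2]), x0 = wf$x[1], t0 = wf$t[1],
               meta = wf$meta)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".csv"), "w")
  on.exit(close(con))
  writeLines(apply(wf$v, 1, function(r) paste(sprintf("%.17g", r),
                                              collapse = ",")), con)
  invisible(stem)
}

#' @rdname write_wavefield
#' @export
read_wavefield <- function(stem) {
  m <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (is.null(m$schema) || m$schema != SCHEMA$wavefield)
    abort(sprintf("'%s.json' has schema '%s', expected '%s'", stem,
                  m$schema %||% "<none>", SCHEMA$wavefield),
          class = "nitioce_schema")
  v <- as.matrix(read.csv(paste0(stem, ".csv"), header = FALSE))
  dimnames(v) <- NULL
  wavefield(x = m$x0 + (seq_len(m$n_x) - 1) * m$dx,
            t = m$t0 + (seq_len(m$n_t) - 1) * m$dt,
            v = v, meta = as.list(m$meta))
}

#' Read / write a Stokes-trajectory volume
#'
#' Long-format CSV with position columns `x`, `y`, depth `depth_um`, and
#' Stokes components `Q`, `U`, `V`, plus a JSON sidecar with schema and
#' generation metadata.
#'
#' @param volume Tibble with the columns above.
#' @param stem Path stem.
#' @param meta Named list stored in the sidecar.
#' @return `read_stokes_volume`: list with `volume` (tibble) and `meta`.
#' @export
write_stokes_volume <- function(volume, stem, meta = list()) {
  stopifnot(all(c("x", "y", "depth_um", "Q", "U", "V") %in% names(volume)))
  jsonlite::write_json(list(schema = SCHEMA$stokes, meta = meta),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  write_full_precision_csv(as.data.frame(volume), paste0(stem, ".csv"))
  invisible(stem)
}

#' @rdname write_stokes_volume
#' @export
read_stokes_volume <- function(stem) {
  m <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (is.null(m$schema) || m$schema != SCHEMA$stokes)
    abort(sprintf("'%s.json' has schema '%s', expected '%s'", stem,
                  m$schema %||% "<none>", SCHEMA$stokes),
          class = "nitioce_schema")
  df <- read.csv(paste0(stem, ".csv"))
  for (col in c("x", "y", "depth_um", "Q", "U", "V"))
    df[[col]] <- read_numeric_col(df, col, paste0(stem, ".csv"))
  list(volume = as_tibble(df), meta = as.list(m$meta))
}
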