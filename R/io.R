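#' Write a modes table
#'
#' CSV with one row per mode: index, frequency in THz, angular frequency in
#' rad/s, and whether the mode is rigid.
#'
#' @param modes a \code{modal_decomposition}.
#' @param file output path.
#' @return The table, invisibly.
#' @export
write_modes_csv <- function(modes, file) {
  stopifnot(inherits(modes, "modal_decomposition"))
  d <- data.frame(mode = seq_along(modes$omega),
                  freq_thz = modes$freq_thz,
                  omega_rad_s = modes$omega,
                  rigid = seq_along(modes$omega) <= modes$n_rigid)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}

#' Write a B-factor comparison table
#'
#' CSV with chain, residue number, residue name, experimental and computed
#' B-factors (A^2).
#'
#' @param struct a \code{\link{cg_structure}}.
#' @param bfactors_calc computed B-factors, length N.
#' @param file output path.
#' @return The table, invisibly.
#' @export
write_bfactor_table <- function(struct, bfactors_calc, file) {
  stopifnot(inherits(struct, "cg_structure"),
            length(bfactors_calc) == struct$n)
  d <- data.frame(chain = struct$chain, resno = struct$resno,
                  resid = struct$resid,
                  b_exp = if (is.null(struct$bfactors)) NA_real_
                          else struct$bfactors,
                  b_calc = bfactors_calc)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}

#' Write a calibration report
#'
#' JSON with the calibrated spring constant and the settings it depends on.
#'
#' @param calibration a \code{\link{calibrate_gamma}} result.
#' @param file output path.
#' @export
write_calibration_json <- function(calibration, file) {
  jsonlite::write_json(
    list(gamma_n_per_m = calibration$gamma,
         temperature_k = calibration$temperature,
         cutoff_a = calibration$cutoff,
         mean_b_exp = calibration$mean_b_exp,
         mean_b_calc = calibration$mean_b_calc),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a trajectory as a numeric table
#'
#' CSV with columns frame, time_ps and the 3N displacement components in
#' Angstrom; excitation metadata is stored in comment header lines
#' (\code{#key: value}) so the file round-trips through
#' \code{\link{read_trajectory_csv}}.
#'
#' @param trajectory an \code{anm_trajectory}.
#' @param file output path.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "anm_trajectory"))
  con <- file(file, "w")
  on.exit(close(con))
  meta <- c(freq_thz = trajectory$excitation$freq_thz,
            damping = paste(trajectory$excitation$damping, collapse = ";"),
            seed = trajectory$excitation$pattern$seed,
            amplitude_n = trajectory$excitation$pattern$amplitude,
            transient_ps = trajectory$transient_ps)
  writeLines(paste0("#", names(meta), ": ", meta), con)
  d <- data.frame(frame = seq_along(trajectory$times_ps),
                  time_ps = trajectory$times_ps, trajectory$disp)
  names(d)[-(1:2)] <- paste0("u", seq_len(ncol(trajectory$disp)))
  utils::write.csv(d, con, row.names = FALSE)
  invisible(file)
}

#' Read a trajectory written by \code{\link{write_trajectory_csv}}
#'
#' @param file path to the CSV.
#' @return An \code{anm_trajectory} (without a structure reference; the
#'   excitation is rebuilt from the header metadata).
#' @export
read_trajectory_csv <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  d <- utils::read.csv(text = lines[-hdr])
  u <- as.matrix(d[, -(1:2), drop = FALSE])
  dimnames(u) <- NULL
  seed <- suppressWarnings(as.integer(meta$seed))
  pat <- structure(list(force = NULL,
                        amplitude = as.numeric(meta$amplitude_n),
                        seed = seed),
                   class = "force_pattern")
  exc <- structure(list(pattern = pat,
                        freq_thz = as.numeric(meta$freq_thz),
                        omega_f = .thz_to_omega(as.numeric(meta$freq_thz)),
                        damping = as.numeric(strsplit(meta$damping,
                                                      ";")[[1]])),
                   class = "harmonic_excitation")
  structure(list(times_ps = d$time_ps, disp = u,
                 transient_ps = as.numeric(meta$transient_ps),
                 excitation = exc, structure = NULL),
            class = "anm_trajectory")
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL per frame, coordinates = reference structure + displacement,
#' readable by standard molecular viewers. Excitation metadata goes into
#' REMARK records.
#'
#' @param trajectory an \code{anm_trajectory} carrying its generating
#'   structure.
#' @param file output path.
#' @param stride keep every stride-th frame (default 1).
#' @export
write_trajectory_pdb <- function(trajectory, file, stride = 1L) {
  stopifnot(inherits(trajectory, "anm_trajectory"))
  s <- trajectory$structure
  if (is.null(s))
    stop("trajectory carries no structure reference")
  keep <- seq(1, nrow(trajectory$disp), by = stride)
  ref <- as.numeric(t(s$xyz))
  xyz <- sweep(trajectory$disp[keep, , drop = FALSE], 2, ref, "+")
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = xyz, resno = s$resno, chain = s$chain,
                   resid = s$resid, elety = rep("CA", s$n),
                   b = if (is.null(s$bfactors)) rep(0, s$n) else s$bfactors)
  remarks <- sprintf(
    "REMARK   3 %s",
    c(paste("forcing frequency (THz):", trajectory$excitation$freq_thz),
      paste("damping ratio:", paste(trajectory$excitation$damping,
                                    collapse = ",")),
      paste("force pattern seed:", trajectory$excitation$pattern$seed),
      paste("transient window (ps):", round(trajectory$transient_ps, 4))))
  writeLines(c(remarks, readLines(tmp)), file)
  unlink(tmp)
  invisible(file)
}

#' Write a coarse-grained structure as a single-model PDB
#'
#' One C-alpha ATOM record per node; the experimental B-factor column is
#' written when present.
#'
#' @param struct a \code{\link{cg_structure}}.
#' @param file output path.
#' @export
write_structure_pdb <- function(struct, file) {
  stopifnot(inherits(struct, "cg_structure"))
  bio3d::write.pdb(file = file, xyz = as.numeric(t(struct$xyz)),
                   resno = struct$resno, chain = struct$chain,
                   resid = struct$resid, elety = rep("CA", struct$n),
                   b = if (is.null(struct$bfactors)) rep(0, struct$n)
                       else struct$bfactors)
  invisible(file)
}

#' Run configuration
#'
#' A flat, serializable record of every setting a run depends on. Written
#' alongside results so any output can be regenerated.
#'
#' @param ... named settings (structure paths, cutoff, gamma or calibrate
#'   flag, temperature, frequency grid, damping list, seed list, window
#'   settings, output directory, preset name, ...).
#' @return Object of class \code{run_config} (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all configuration entries must be named")
  structure(cfg, class = "run_config")
}

#' @export
#' @rdname run_config
#' @param config a \code{run_config}.
#' @param file output path (YAML).
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @export
#' @rdname run_config
read_run_config <- function(file) {
  structure(yaml::read_yaml(file), class = "run_config")
}
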