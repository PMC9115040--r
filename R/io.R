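## Plain-text table formats: '#'-prefixed metadata headers, tab-separated
## numeric columns.  The shapes mirror common ELF / IMFP / SDCS data
## releases so the files are directly usable by track-structure codes.

#' Write an ELF surface to a plain-text table
#'
#' Format: UTF-8, `#`-prefixed header lines declaring units, the q grid
#' and provenance, then one row per energy with tab-separated columns
#' (energy, one ELF column per q).
#'
#' @param surface an [elf_surface()].
#' @param path output file path.
#' @param energy_unit `"eV"` (default) or `"hartree"` for the energy
#'   column written to disk; the header records the choice so reading
#'   converts back.
#' @return `path`, invisibly.
#' @export
write_elf_table <- function(surface, path, energy_unit = c("eV", "hartree")) {
  energy_unit <- match.arg(energy_unit)
  eg <- surface$energy_grid
  if (energy_unit == "hartree") eg <- ev_to_ha(eg)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# elfxs ELF table",
    paste0("# energy_unit: ", energy_unit),
    "# q_unit: au",
    paste0("# optical_q: ", format(surface$optical_q, digits = 17)),
    paste0("# q_grid: ", paste(format(surface$q_grid, digits = 17),
                               collapse = "\t")),
    paste0("# provenance: ",
           paste(names(surface$provenance),
                 vapply(surface$provenance, function(x)
                   paste(format(x), collapse = " "), ""),
                 sep = "=", collapse = "; ")),
    paste0("# columns: energy\t",
           paste0("elf_q", seq_along(surface$q_grid), collapse = "\t"))
  ), con)
  m <- cbind(eg, surface$values)
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(rows, con)
  invisible(path)
}

.parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-zA-Z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read an ELF surface from a plain-text table
#'
#' Inverse of [write_elf_table()].  Units declared in the header are
#' honoured (energies in hartree are converted to eV).  Negative ELF
#' cells and non-uniform energy spacing are rejected.
#'
#' @param path file path.
#' @return an [elf_surface()].
#' @export
read_elf_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  kv <- .parse_header(lines)
  if (is.null(kv$q_grid)) stop("header lacks a `q_grid:` line")
  if (is.null(kv$energy_unit)) stop("header lacks an `energy_unit:` line")
  q_grid <- as.numeric(strsplit(kv$q_grid, "[\t ]+")[[1]])
  data <- lines[!grepl("^#", lines) & nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(data, "\t"), as.numeric))
  if (ncol(m) != length(q_grid) + 1)
    stop("column count does not match the declared q grid")
  eg <- m[, 1]
  if (tolower(kv$energy_unit) %in% c("hartree", "ha", "au"))
    eg <- ha_to_ev(eg)
  vals <- m[, -1, drop = FALSE]
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative ELF value in row %d, q column %d of %s",
                 bad[1], bad[2], path))
  }
  de <- diff(eg)
  if (length(de) && max(abs(de - de[1])) > 1e-6 * abs(de[1]))
    stop("energy grid spacing is not uniform")
  optical_q <- if (!is.null(kv$optical_q)) as.numeric(kv$optical_q)
  else min(q_grid)
  elf_surface(eg, q_grid, vals, optical_q = optical_q,
              provenance = list(source = path))
}

#' Write cross-section tables
#'
#' Writes `imfp.tsv` (T, IMFP), `stopping.tsv` (T, S_e) and, for each
#' supplied SDCS curve, `sdcs_T<energy>.tsv` (E, dSigma/dE and per-channel
#' columns when present), all with `#` metadata headers.
#'
#' @param xs an `xs_table` from [total_cross_section()] /
#'   [stopping_power()].
#' @param dir output directory (created if needed).
#' @param sdcs_curves optional list of `sdcs_curve` or `sdcs_channel_set`
#'   objects.
#' @return character vector of written paths, invisibly.
#' @export
write_xs_tables <- function(xs, dir, sdcs_curves = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  hdr <- function(what, unit) c(
    paste0("# elfxs ", what, " table"),
    paste0("# units: T eV, value ", unit),
    paste0("# emin_mode: ", attr(xs, "emin_mode")),
    sprintf("# E_gap: %g eV, E_F: %g eV", attr(xs, "E_gap"), attr(xs, "E_F")))
  wr <- function(fname, header, df) {
    p <- file.path(dir, fname)
    con <- file(p, "w", encoding = "UTF-8")
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    close(con)
    p
  }
  paths <- c(paths,
             wr("imfp.tsv", hdr("IMFP", "nm"), xs[, c("T", "imfp")]),
             wr("stopping.tsv", hdr("stopping power", "eV/nm"),
                xs[, c("T", "stopping")]),
             wr("sigma.tsv", hdr("total inelastic cross section", "1/nm"),
                xs[, c("T", "sigma_total")]))
  for (sc in sdcs_curves) {
    tt <- attr(sc, "T")
    fn <- sprintf("sdcs_T%g.tsv", tt)
    df <- as.data.frame(sc)
    paths <- c(paths, wr(fn, c(
      "# elfxs SDCS table",
      sprintf("# T: %g eV", tt),
      "# units: energy eV, values 1/(nm eV)"), df))
  }
  invisible(paths)
}

#' Write a run configuration
#'
#' Key/value text format (`key = value`, `#` comments, vectors
#' comma-separated) capturing every numerical policy of a pipeline run, so
#' rerunning from the serialized copy reproduces outputs bit-identically.
#'
#' @param config named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- c("# elfxs run configuration",
             vapply(names(config), function(k) {
               v <- config[[k]]
               paste0(k, " = ", paste(format(v, digits = 17), collapse = ", "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration
#'
#' @param path file written by [write_run_config()] (or hand-authored in
#'   the same key = value format).
#' @return named list; numeric-looking values are converted, commas split
#'   vectors.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", l)
    vals <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[m[2]]] <- if (!anyNA(num)) num else vals
  }
  out
}
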