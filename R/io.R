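# TSV readers/writers for titrations, spectra and event tables. Headers are
# "# key: value" comment lines recording generating parameters, so a file
# round-trips with its provenance.

write_header_comments <- function(con, params) {
  if (is.null(params)) return(invisible())
  for (k in names(params)) {
    v <- params[[k]]
    if (is.list(v)) v <- paste(unlist(v), collapse = ",")
    writeLines(sprintf("# %s: %s", k, paste(format(v, digits = 15),
                                            collapse = ",")), con)
  }
}

#' Write / read a titration TSV
#'
#' Columns `titrant_nM`, `FP_mP`, `replicate`; `#`-prefixed header comments
#' record the probe concentration and any generating parameters.
#'
#' @param curve An `rs_titration`.
#' @param path File path.
#' @return `path` invisibly (write); an `rs_titration` (read).
#' @export
write_titration_tsv <- function(curve, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  write_header_comments(con, c(list(probe_nM = attr(curve, "probe_nM")),
                               attr(curve, "gen_params")))
  utils::write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_tsv
#' @export
read_titration_tsv <- function(path) {
  hdr <- read_header_comments(path)
  df <- utils::read.delim(path, comment.char = "#")
  probe <- as.numeric(hdr[["probe_nM"]])
  if (!length(probe) || is.na(probe)) {
    stop("titration TSV lacks a '# probe_nM:' header", call. = FALSE)
  }
  titration_curve(df$titrant_nM, df$FP_mP, probe,
                  if (is.null(df$replicate)) 1L else df$replicate)
}

read_header_comments <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' Write / read an emission-spectra series TSV
#'
#' Long format with columns `wavelength_nm`, `intensity`, `urea_M`.
#'
#' @param spectra List of [emission_spectrum()] objects.
#' @param path File path.
#' @return `path` invisibly (write); a list of spectra (read).
#' @export
write_spectra_tsv <- function(spectra, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  gp <- attr(spectra, "gen_params")
  if (!is.null(gp)) {
    write_header_comments(con, gp[c("dg", "m", "n_base", "d_base",
                                    "temperature", "noise_sd", "seed")])
  }
  long <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(wavelength_nm = s$wavelength_nm, intensity = s$intensity,
               urea_M = attr(s, "urea_M"))
  }))
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_tsv
#' @export
read_spectra_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  lapply(split(df, df$urea_M), function(d) {
    emission_spectrum(d$wavelength_nm, d$intensity, urea = d$urea_M[1])
  })
}

#' Write an interaction event table as TSV
#'
#' @param events Event data frame (optionally with a `frame` column).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  cols <- intersect(c("frame", "kind", "span", "chain_a", "res_a",
                      "chain_b", "res_b", "distance", "angle"),
                    names(events))
  utils::write.table(events[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write summary tables for binding fits and interaction counts
#'
#' Emits diff-stable TSV tables: a dissociation-constant table (Kd to 2
#' significant figures with its SD; non-determinable fits print the literal
#' `too weak to be determined`) and, when census results are supplied, an
#' interaction-count table (2 decimals).
#'
#' @param binding_fits Named list of `rs_binding_fit` objects; names are
#'   used as the titrant label. May be empty.
#' @param counts An `rs_replicate_summary` (or `NULL`).
#' @param dir Output directory (created if needed).
#' @param probe_label Label for the fluorophore-labelled probe column.
#' @return Character vector of files written, invisibly.
#' @export
write_summary_tables <- function(binding_fits = list(), counts = NULL,
                                 dir = ".", probe_label = "probe") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  tab <- data.frame(probe = character(), titrant = character(),
                    Kd_nM = character(), SD_nM = character(),
                    determinable = logical(), stringsAsFactors = FALSE)
  for (nm in names(binding_fits)) {
    f <- binding_fits[[nm]]
    if (isTRUE(f$determinable)) {
      kd_txt <- format(signif(f$kd, 2), scientific = FALSE, trim = TRUE)
      sd_txt <- if (is.finite(f$kd_sd)) {
        format(signif(f$kd_sd, 2), scientific = FALSE, trim = TRUE)
      } else ""
    } else {
      kd_txt <- "too weak to be determined"
      sd_txt <- ""
    }
    tab <- rbind(tab, data.frame(probe = probe_label, titrant = nm,
                                 Kd_nM = kd_txt, SD_nM = sd_txt,
                                 determinable = isTRUE(f$determinable),
                                 stringsAsFactors = FALSE))
  }
  path <- file.path(dir, "binding_table.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, path)

  if (!is.null(counts)) {
    ct <- data.frame(kind = counts$kind, span = counts$span,
                     mean = sprintf("%.2f", counts$mean),
                     sd = sprintf("%.2f", counts$sd),
                     stringsAsFactors = FALSE)
    path <- file.path(dir, "counts_table.tsv")
    utils::write.table(ct, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}
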