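#' Read an MGF file
#'
#' Parses the Mascot Generic Format dialect used by search engines:
#' `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and `CHARGE`
#' headers followed by `m/z intensity` peak lines.
#'
#' @param path Path to an MGF file.
#' @return List of [spectrum()] objects in file order. Blocks without a
#'   `PEPMASS` are skipped with a warning naming the block; an empty file
#'   yields an empty list with a warning.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) == 0L) {
    warning("no spectra found in ", path)
    return(list())
  }
  if (length(starts) != length(ends) || any(ends < starts))
    stop("unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(starts))
  kept <- logical(length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    is_header <- grepl("=", block, fixed = TRUE)
    headers <- block[is_header]
    key <- sub("=.*$", "", headers)
    val <- sub("^[^=]*=", "", headers)
    title <- if ("TITLE" %in% key) val[match("TITLE", key)] else sprintf("index=%d", i)
    if (!"PEPMASS" %in% key) {
      warning(sprintf("MGF block %d ('%s') lacks PEPMASS; skipped", i, title))
      next
    }
    pepmass <- as.numeric(strsplit(val[match("PEPMASS", key)], "[ \t]+")[[1]][1])
    charge <- 2L
    if ("CHARGE" %in% key)
      charge <- as.integer(sub("[+-]$", "", val[match("CHARGE", key)]))
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    fields <- strsplit(trimws(peak_lines), "[ \t]+")
    mz <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
    intensity <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
    out[[i]] <- spectrum(title, pepmass, charge, peak_table(mz, intensity))
    kept[i] <- TRUE
  }
  out[kept]
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}
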