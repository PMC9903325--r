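# NIST-style MSP text dialect. Entries look like
#
#   Name: PEPTIDEK/2
#   MW: 930.4960
#   PrecursorMZ: 466.2553
#   Comment: Charge=2 Mods=1/3,C,Carbamidomethyl Decoy=true Signature=...
#   Num peaks: 4
#   175.1190<TAB>1234.00<TAB>"y1/0.25ppm"
#
# Annotation grammar (one annotation kept per peak):
#   series token  y3, b5, a2, Int3-6   (Int bounds 1-based inclusive residues)
#   charge        ^2 when > 1
#   neutral loss  -18.0 (H2O) or -17.0 (NH3)
#   error         /<ppm>ppm
# Mods= uses 1-based residue positions (N-term / C-term for terminal mods).

# vectorized over the rows of a peak table; "" for unannotated peaks
ann_strings <- function(pk, peptide) {
  out <- character(nrow(pk))
  ann <- !is.na(pk$ann_series)
  if (!any(ann)) return(out)
  base <- ifelse(pk$ann_series[ann] == "internal",
                 sprintf("Int%d-%d", pk$ann_start[ann] + 1L, pk$ann_end[ann]),
                 paste0(pk$ann_series[ann], pk$ann_ordinal[ann]))
  z <- pk$ann_charge[ann]
  base <- ifelse(z > 1L, sprintf("%s^%d", base, z), base)
  loss <- pk$ann_loss[ann]
  base <- ifelse(!is.na(loss) & loss > 0, sprintf("%s-%.1f", base, loss), base)
  theo <- annotation_mz(peptide, pk$ann_series[ann], pk$ann_ordinal[ann],
                        z, loss, pk$ann_start[ann], pk$ann_end[ann])
  out[ann] <- sprintf("\"%s/%.2fppm\"", base, 1e6 * (pk$mz[ann] - theo) / theo)
  out
}

parse_ann_string <- function(txt) {
  txt <- gsub("\"", "", txt)
  body <- sub("/.*$", "", txt)
  m <- regmatches(body, regexec(
    "^(Int([0-9]+)-([0-9]+)|([yba])([0-9]+))(\\^([0-9]+))?(-([0-9.]+))?$", body))[[1]]
  if (length(m) == 0L) return(NULL)
  chg <- if (nzchar(m[8])) as.integer(m[8]) else 1L
  loss <- if (nzchar(m[10])) as.numeric(m[10]) else 0
  # losses are serialized rounded; map back to exact neutral-loss masses
  if (loss > 0) loss <- if (abs(loss - 18) < 0.5) H2O_MASS else NH3_MASS
  if (nzchar(m[3])) {
    list(series = "internal", ordinal = NA_integer_, charge = chg, loss = loss,
         start = as.integer(m[3]) - 1L, end = as.integer(m[4]))
  } else {
    list(series = m[5], ordinal = as.integer(m[6]), charge = chg, loss = loss,
         start = NA_integer_, end = NA_integer_)
  }
}

serialize_mods <- function(mods) {
  if (nrow(mods) == 0L) return("Mods=0")
  toks <- vapply(seq_len(nrow(mods)), function(i) {
    pos <- if (!is.na(mods$terminus[i])) paste0(mods$terminus[i], "-term")
           else as.character(mods$position[i] + 1L)
    aa <- if (!is.na(mods$position[i])) attr(mods, "residues")[i] else "-"
    sprintf("%s,%s,%s", pos, aa, mods$name[i])
  }, character(1))
  paste0("Mods=", nrow(mods), "/", paste(toks, collapse = "/"))
}

parse_mods <- function(token, sequence) {
  if (token == "0" || !nzchar(token)) return(NULL)
  parts <- strsplit(token, "/", fixed = TRUE)[[1]]
  k <- as.integer(parts[1])
  toks <- parts[-1]
  if (length(toks) != k) stop("Mods count mismatch")
  pos <- integer(0); term <- character(0); delta <- numeric(0); nm <- character(0)
  for (t in toks) {
    f <- strsplit(t, ",", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop("bad Mods token: ", t)
    if (!f[3] %in% names(MOD_MASS)) stop("unknown modification name: ", f[3])
    if (grepl("-term$", f[1])) {
      pos <- c(pos, NA_integer_); term <- c(term, sub("-term$", "", f[1]))
    } else {
      pos <- c(pos, as.integer(f[1]) - 1L); term <- c(term, NA_character_)
    }
    delta <- c(delta, unname(MOD_MASS[f[3]])); nm <- c(nm, f[3])
  }
  data.frame(position = pos, terminus = term, mass_delta = delta, name = nm,
             stringsAsFactors = FALSE)
}

#' Read an MSP spectral library
#'
#' Parses a NIST-style text MSP library into annotated library entries.
#' Peptide sequence and charge come from `Name:`, modifications from the
#' `Mods=` Comment token, the decoy flag from `Decoy=true`. Peak annotation
#' strings matching the supported grammar are parsed; others are left
#' unannotated.
#'
#' @param path Path to an MSP file.
#' @return List of [library_entry()] objects in file order. Entries whose
#'   peak count disagrees with `Num peaks:` are skipped with a warning;
#'   an unparseable `Mods=` token keeps the entry with an empty
#'   modification list and a warning.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^Name:", lines)
  if (length(starts) == 0L) return(list())
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    entry <- tryCatch(parse_msp_entry(block),
                      error = function(e) {
                        warning(sprintf("MSP entry %d skipped: %s", i, conditionMessage(e)))
                        NULL
                      })
    if (!is.null(entry)) out[[length(out) + 1L]] <- entry
  }
  out
}

parse_msp_entry <- function(block) {
  name <- trimws(sub("^Name:", "", block[1]))
  seq_charge <- strsplit(name, "/", fixed = TRUE)[[1]]
  sequence <- seq_charge[1]
  charge <- as.integer(seq_charge[2])
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), block, value = TRUE)
    if (length(ln) == 0L) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  comment <- get_field("Comment")
  tokens <- if (is.na(comment)) character() else strsplit(comment, " +")[[1]]
  tok_val <- function(key) {
    hit <- grep(paste0("^", key, "="), tokens, value = TRUE)
    if (length(hit) == 0L) NA_character_ else sub(paste0("^", key, "="), "", hit[1])
  }
  mods <- NULL
  mods_tok <- tok_val("Mods")
  if (!is.na(mods_tok)) {
    mods <- tryCatch(parse_mods(mods_tok, sequence), error = function(e) {
      warning("unparseable Mods token '", mods_tok, "'; modifications dropped")
      NULL
    })
  }
  pep <- peptide(sequence, charge, mods)

  npk_line <- grep("^Num peaks:", block)
  if (length(npk_line) == 0L) stop("missing 'Num peaks:'")
  n_declared <- as.integer(trimws(sub("^Num peaks:", "", block[npk_line[1]])))
  peak_lines <- block[(npk_line[1] + 1L):length(block)]
  peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
  if (length(peak_lines) != n_declared)
    stop(sprintf("Num peaks mismatch for %s: declared %d, found %d",
                 name, n_declared, length(peak_lines)))

  fields <- strsplit(trimws(peak_lines), "[ \t]+")
  pk <- peak_table(vapply(fields, function(f) as.numeric(f[1]), numeric(1)),
                   vapply(fields, function(f) as.numeric(f[2]), numeric(1)))
  # annotation strings: re-associate after sorting by locating original order
  ord <- order(vapply(fields, function(f) as.numeric(f[1]), numeric(1)))
  for (j in seq_along(fields)) {
    f <- fields[[ord[j]]]
    if (length(f) >= 3L) {
      ann <- parse_ann_string(paste(f[-(1:2)], collapse = " "))
      if (!is.null(ann)) {
        pk$ann_series[j] <- ann$series
        pk$ann_ordinal[j] <- ann$ordinal
        pk$ann_charge[j] <- ann$charge
        pk$ann_loss[j] <- ann$loss
        pk$ann_start[j] <- ann$start
        pk$ann_end[j] <- ann$end
      }
    }
  }
  pmz <- suppressWarnings(as.numeric(get_field("PrecursorMZ")))
  if (is.na(pmz)) pmz <- precursor_mz(pep)
  sp <- spectrum(name, pmz, charge, pk)
  ent <- library_entry(pep, sp, is_decoy = identical(tok_val("Decoy"), "true"),
                       origin = if (is.na(tok_val("Origin"))) "" else tok_val("Origin"))
  sig <- tok_val("Signature")
  if (!is.na(sig)) attr(ent, "signature") <- sig
  ent
}

#' Write library entries to an MSP file
#'
#' Round-trips through [read_msp()]: sequences, charges, peak m/z (4
#' decimals), intensities and annotations are reproduced; decoy entries
#' carry a `Decoy=true` Comment token. Output formatting is fixed, so the
#' same entries always produce byte-identical files.
#'
#' @param entries List of [library_entry()] objects.
#' @param path Output path.
#' @param signature Optional annotation signature stored in each Comment.
#' @return `path`, invisibly.
#' @export
write_msp <- function(entries, path, signature = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ent in entries) {
    pep <- ent$peptide
    mods <- pep$modifications
    if (nrow(mods))
      attr(mods, "residues") <- ifelse(is.na(mods$position), "-",
        substring(pep$sequence, mods$position + 1L, mods$position + 1L))
    comment <- paste(c(
      sprintf("Charge=%d", pep$charge),
      serialize_mods(mods),
      if (ent$is_decoy) "Decoy=true",
      if (nzchar(ent$origin)) paste0("Origin=", gsub(" ", "_", ent$origin)),
      if (!is.null(signature)) paste0("Signature=", signature)
    ), collapse = " ")
    pk <- ent$spectrum$peaks
    ann <- ann_strings(pk, pep)
    peak_lines <- sprintf("%.4f\t%.6f%s", pk$mz, pk$intensity,
                          ifelse(nzchar(ann), paste0("\t", ann), ""))
    writeLines(c(
      sprintf("Name: %s/%d", pep$sequence, pep$charge),
      sprintf("MW: %.4f", peptide_mass(pep)),
      sprintf("PrecursorMZ: %.6f", ent$spectrum$precursor_mz),
      paste0("Comment: ", comment),
      sprintf("Num peaks: %d", nrow(pk)),
      peak_lines, ""
    ), con)
  }
  invisible(path)
}
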