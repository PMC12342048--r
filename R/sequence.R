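#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 canonical amino-acid
#' letters. Residue numbering is 1-based on the precursor exactly as stored in
#' the file (no signal-peptide offset is applied). The accession is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) any non-canonical residue letter is an
#'   error naming the residue and its position; if `FALSE` offending records
#'   are kept and flagged in the `clean` column with a warning.
#' @return A tibble with one row per record: `accession`, `description`,
#'   `sequence`, `length`, `clean`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P example", "MKR"), fa)
#' read_fasta(fa)
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  recs <- tibble(
    accession = stringr::str_extract(headers, "^\\S+"),
    description = stringr::str_trim(stringr::str_remove(headers, "^\\S+")),
    sequence = unname(seqs),
    length = unname(nchar(seqs))
  )
  if (any(recs$length == 0)) abort("FASTA contains an empty sequence record")
  bad <- stringr::str_locate(recs$sequence, paste0("[^", paste(AA20, collapse = ""), "]"))
  recs$clean <- is.na(bad[, "start"])
  if (!all(recs$clean)) {
    i <- which(!recs$clean)[1]
    pos <- bad[i, "start"]
    msg <- sprintf("non-canonical residue '%s' at position %d of %s",
                   substr(recs$sequence[i], pos, pos), pos, recs$accession[i])
    if (strict) abort(msg) else warn(msg)
  }
  recs
}

# accept a one-row protein tibble (from read_fasta), a named list, or a bare
# sequence string; returns list(accession, sequence)
as_protein <- function(protein) {
  if (is.character(protein) && length(protein) == 1 && !grepl("[^A-Za-z]", protein)) {
    return(list(accession = "protein", sequence = toupper(protein)))
  }
  if (is.data.frame(protein)) {
    if (nrow(protein) != 1)
      abort("expected a single protein record; subset the FASTA tibble to one row")
    return(list(accession = protein$accession[[1]], sequence = protein$sequence[[1]]))
  }
  if (is.list(protein) && !is.null(protein$sequence)) {
    return(list(accession = protein$accession %||% "protein",
                sequence = protein$sequence))
  }
  abort("cannot interpret `protein`: supply a read_fasta() row or a sequence string")
}

#' Locate a peptide within a protein sequence
#'
#' Finds all exact-match spans of `peptide` in the protein, in ascending start
#' order, with 1-based inclusive coordinates and the flanking residues filled
#' in (`"-"` marks a protein terminus). An absent peptide yields a zero-row
#' tibble; the caller decides whether that is an error.
#'
#' @param protein A one-row tibble from [read_fasta()], a list with
#'   `accession`/`sequence`, or a plain sequence string.
#' @param peptide Non-empty amino-acid string.
#' @return Tibble with columns `accession`, `peptide`, `start`, `end`,
#'   `preceding`, `following`.
#' @export
locate_peptide <- function(protein, peptide) {
  pr <- as_protein(protein)
  if (!is.character(peptide) || length(peptide) != 1 || nchar(peptide) == 0)
    abort("`peptide` must be a single non-empty string")
  peptide <- toupper(peptide)
  hits <- gregexpr(peptide, pr$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    return(tibble(accession = character(), peptide = character(),
                  start = integer(), end = integer(),
                  preceding = character(), following = character()))
  }
  start <- as.integer(hits)
  end <- start + nchar(peptide) - 1L
  L <- nchar(pr$sequence)
  tibble(
    accession = pr$accession, peptide = peptide, start = start, end = end,
    preceding = ifelse(start == 1L, TERMINUS, substring(pr$sequence, start - 1L, start - 1L)),
    following = ifelse(end == L, TERMINUS, substring(pr$sequence, end + 1L, end + 1L))
  )
}

#' Classify peptide termini by trypsin specificity
#'
#' A terminus is `tryptic` when it conforms to trypsin specificity (cleavage
#' C-terminal to K or R, optionally suppressed before proline), a
#' `protein_terminus` when the peptide abuts the protein end (marker `"-"`),
#' and `nontryptic` otherwise. The N side is tryptic iff the preceding residue
#' is K/R (and, under the proline rule, the peptide does not start with P);
#' the C side iff the peptide's last residue is K/R (and, under the proline
#' rule, the following residue is not P).
#'
#' Protein termini are deliberately non-evidentiary: a peptide ending at the
#' mature terminus is not proteolytic evidence, so for overall status they
#' count like tryptic termini. A peptide is `fully` tryptic when both termini
#' are tryptic or protein termini, `semi` when exactly one terminus is
#' nontryptic, and `non` when both are.
#'
#' @param peptides A tibble with columns `peptide`, `preceding`, `following`
#'   (as produced by [locate_peptide()] or [read_quant_table()]).
#' @param proline_rule Suppress cleavage before proline (default `TRUE`).
#' @return Input tibble with columns `n_term`, `c_term`, `tryptic_status`.
#' @export
classify_termini <- function(peptides, proline_rule = TRUE) {
  stopifnot(all(c("peptide", "preceding", "following") %in% names(peptides)))
  first_res <- substr(peptides$peptide, 1, 1)
  last_res <- substring(peptides$peptide, nchar(peptides$peptide))
  n_tryp <- peptides$preceding %in% c("K", "R") &
    (!proline_rule | first_res != "P")
  c_tryp <- last_res %in% c("K", "R") &
    (!proline_rule | peptides$following != "P")
  n_term <- dplyr::case_when(
    peptides$preceding == TERMINUS ~ "protein_terminus",
    n_tryp ~ "tryptic",
    TRUE ~ "nontryptic")
  c_term <- dplyr::case_when(
    peptides$following == TERMINUS ~ "protein_terminus",
    c_tryp ~ "tryptic",
    TRUE ~ "nontryptic")
  n_non <- (n_term == "nontryptic") + (c_term == "nontryptic")
  peptides |>
    mutate(n_term = n_term, c_term = c_term,
           tryptic_status = c("fully", "semi", "non")[n_non + 1L])
}

#' In-silico tryptic digestion
#'
#' Enumerates all fully tryptic peptides of a protein with up to `max_missed`
#' internal missed cleavage sites. Cleavage is C-terminal to K/R, optionally
#' suppressed before proline. Zero-missed peptides tile the protein exactly.
#'
#' @inheritParams locate_peptide
#' @param max_missed Maximum number of internal missed cleavages (>= 0).
#' @param proline_rule Suppress cleavage before proline (default `TRUE`).
#' @return Tibble of peptide spans with `n_missed`.
#' @export
tryptic_digest <- function(protein, max_missed = 0, proline_rule = TRUE) {
  pr <- as_protein(protein)
  if (max_missed < 0) abort("`max_missed` must be >= 0")
  res <- strsplit(pr$sequence, "")[[1]]
  L <- length(res)
  nxt <- c(res[-1], "")
  cut <- which(res %in% c("K", "R") & (!proline_rule | nxt != "P"))
  cut <- cut[cut < L]                     # a C-terminal K/R ends the last piece anyway
  ends0 <- c(cut, L)
  starts0 <- c(1L, cut + 1L)
  n0 <- length(ends0)
  out <- list()
  for (m in 0:max_missed) {
    if (m >= n0) break
    i <- seq_len(n0 - m)
    out[[m + 1]] <- tibble(start = starts0[i], end = ends0[i + m], n_missed = m)
  }
  spans <- bind_rows(out)
  tibble(
    accession = pr$accession,
    peptide = substring(pr$sequence, spans$start, spans$end),
    start = spans$start, end = spans$end, n_missed = spans$n_missed,
    preceding = ifelse(spans$start == 1L, TERMINUS,
                       substring(pr$sequence, spans$start - 1L, spans$start - 1L)),
    following = ifelse(spans$end == L, TERMINUS,
                       substring(pr$sequence, spans$end + 1L, spans$end + 1L))
  )
}

#' Average mass and A280 extinction coefficient of a peptide
#'
#' Average molecular mass from standard average residue masses plus one water,
#' and the molar extinction coefficient at 280 nm from the Trp/Tyr/cystine
#' increments (5500/1490/125 M-1 cm-1). When `reduced = TRUE` the cystine term
#' is dropped; otherwise all cysteines are assumed paired (`floor(nCys / 2)`
#' cystines).
#'
#' @param sequence Amino-acid string(s), canonical residues only.
#' @param reduced Assume free thiols (default `FALSE`).
#' @return Tibble with `sequence`, `avg_mass` (Da), `extinction_280`
#'   (M-1 cm-1).
#' @export
#' @examples
#' protparam_properties("WY")  # 5500 + 1490
protparam_properties <- function(sequence, reduced = FALSE) {
  sequence <- toupper(sequence)
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"), sequence)
  if (any(bad)) abort(paste0("non-canonical residue in: ", sequence[bad][1]))
  counts <- function(s, aa) stringr::str_count(s, stringr::fixed(aa))
  mass <- map_dbl(sequence, function(s) {
    sum(AA_AVG_MASS[strsplit(s, "")[[1]]]) + WATER_AVG_MASS
  })
  ext <- 5500 * counts(sequence, "W") + 1490 * counts(sequence, "Y") +
    if (reduced) 0 else 125 * (counts(sequence, "C") %/% 2)
  tibble(sequence = sequence, avg_mass = mass, extinction_280 = ext)
}
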