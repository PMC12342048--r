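# shared test utilities: tiny builders and independent brute-force oracles

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

fixture_path <- function(name) {
  system.file("extdata", name, package = "degradomics", mustWork = TRUE)
}

scaffold_protein <- function() {
  read_fasta(fixture_path("comp_scaffold_synthetic.fasta"))
}

write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# a quant observation row; NA abundance = not detected
obs <- function(peptide, preceding, following, active = NA, control = NA) {
  tibble::tibble(peptide = peptide, preceding = preceding,
                 following = following,
                 abundance_active = as.numeric(active),
                 abundance_control = as.numeric(control))
}

# records carrying given both-group log2 ratios (fully tryptic context),
# plus optional extra rows, ready for compute_zscores()
both_group_records <- function(log2_ratios, extra = NULL) {
  base <- 1e5
  n <- length(log2_ratios)
  ids <- chartr("0123456789", "ACDEFGHILM", sprintf("%06d", seq_len(n)))
  rows <- tibble::tibble(
    peptide = paste0("GSAVLNTE", ids, "K"),
    preceding = "K", following = "T",
    abundance_active = base * 2^log2_ratios,
    abundance_control = base)
  if (n == 0) rows <- rows[0, ]
  dplyr::bind_rows(rows, extra) |>
    aggregate_observations() |>
    compute_ratios() |>
    classify_termini()
}

# independent brute-force tryptic peptide enumeration over all substrings
brute_tryptic_peptides <- function(sequence, max_missed, proline_rule = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  is_cut <- function(i) {            # cleavable bond after residue i
    i >= 1 && i < L && res[i] %in% c("K", "R") &&
      (!proline_rule || res[i + 1] != "P")
  }
  out <- character()
  for (i in 1:L) for (j in i:L) {
    if (!(i == 1 || is_cut(i - 1))) next
    if (!(j == L || is_cut(j))) next
    internal <- if (j > i) sum(vapply(i:(j - 1), is_cut, logical(1))) else 0
    if (internal <= max_missed) out <- c(out, paste0(i, ":", j))
  }
  sort(out)
}

# independent brute-force site caller: every semi-tryptic candidate boundary
# checked directly against the selection rule (no package caller involved)
brute_force_sites <- function(quant, sequence, z_threshold = 2) {
  agg <- stats::aggregate(
    cbind(abundance_active, abundance_control) ~ peptide + preceding + following,
    data = as.data.frame(quant), FUN = function(x) sum(x, na.rm = TRUE),
    na.action = stats::na.pass)
  act <- ifelse(is.na(agg$abundance_active) | agg$abundance_active <= 0,
                NA, agg$abundance_active)
  ctl <- ifelse(is.na(agg$abundance_control) | agg$abundance_control <= 0,
                NA, agg$abundance_control)
  both <- !is.na(act) & !is.na(ctl)
  l2 <- ifelse(both, log2(act / ctl), ifelse(!is.na(act), log2(100), NA))
  m <- mean(l2[both]); s <- stats::sd(l2[both])
  z <- (l2 - m) / s
  res <- strsplit(sequence, "")[[1]]; L <- length(res)
  sites <- integer()
  for (i in seq_len(nrow(agg))) {
    p <- agg$peptide[i]
    st <- regexpr(p, sequence, fixed = TRUE)[1]
    if (st == -1) next
    en <- st + nchar(p) - 1
    first <- substr(p, 1, 1); last <- substring(p, nchar(p))
    n_ok <- st == 1 || (res[st - 1] %in% c("K", "R") && first != "P")
    c_ok <- en == L || (last %in% c("K", "R") && res[en + 1] != "P")
    semi <- xor(n_ok, c_ok)
    if (!semi) next
    sig <- (!is.na(act[i]) && is.na(ctl[i])) || (both[i] && z[i] > z_threshold)
    if (!sig) next
    p1 <- if (!n_ok) st - 1 else en
    if (p1 >= 1 && p1 + 1 <= L) sites <- c(sites, p1)
  }
  sort(unique(sites))
}
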