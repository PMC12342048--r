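#' Background amino-acid composition (human Swiss-Prot)
#'
#' Percentage composition of the 20 canonical amino acids in human Swiss-Prot
#' entries, used as the default reference set for positional enrichment
#' (normalized to sum exactly to 100). Override with any named 20-vector of
#' percentages to use a different reference proteome.
#'
#' @return Named numeric vector of percentages summing to 100.
#' @export
aa_background <- function() {
  comp <- c(
    A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
    G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
    P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87)
  100 * comp / sum(comp)
}

position_labels <- function(window) {
  c(paste0("P", window:1), paste0("P", 1:window, "'"))
}

#' Extract P4-P4' windows around cleavage sites
#'
#' Reads the substrate residues flanking each P1-P1' boundary. Positions that
#' run off a protein terminus carry the gap marker `"-"`.
#'
#' @param sites A `site_calls` tibble (or any tibble with `accession`,
#'   `p1_pos`).
#' @param proteins Tibble of substrates from [read_fasta()] (matched by
#'   accession), or a single protein used for every site.
#' @param window Number of residues on each side of the scissile bond
#'   (default 4, i.e. P4-P4').
#' @return Tibble with one row per site x position: `accession`, `p1_pos`,
#'   `position` (ordered factor P4..P4'), `residue`.
#' @export
extract_windows <- function(sites, proteins, window = 4) {
  if (nrow(sites) == 0)
    return(tibble(accession = character(), p1_pos = integer(),
                  position = character(), residue = character()))
  labs <- position_labels(window)
  get_protein <- function(acc) {
    if (is.data.frame(proteins) && nrow(proteins) > 1) {
      hit <- proteins[proteins$accession == acc, , drop = FALSE]
      if (nrow(hit) == 0) abort(paste0("no substrate with accession ", acc))
      as_protein(hit[1, ])
    } else as_protein(proteins)
  }
  rows <- map(seq_len(nrow(sites)), function(i) {
    pr <- get_protein(sites$accession[i])
    L <- nchar(pr$sequence)
    p1 <- sites$p1_pos[i]
    if (p1 < 1 || p1 + 1 > L) abort(sprintf("site %d outside sequence", p1))
    pos <- (p1 - window + 1):(p1 + window)
    res <- ifelse(pos >= 1 & pos <= L, substring(pr$sequence, pos, pos), TERMINUS)
    tibble(accession = pr$accession, p1_pos = p1, position = labs, residue = res)
  })
  out <- list_rbind(rows)
  out$position <- factor(out$position, levels = labs)
  out
}

#' Positional amino-acid enrichment against a background composition
#'
#' IceLogo-style percentage scoring: at each window position, the observed
#' frequency (%) of each residue among non-gap entries is compared with the
#' background composition. Significance is a two-sided z-test from the normal
#' approximation to the binomial with p0 = background/100 and n = non-gap
#' count at that position, at level `alpha`, with no multiple-testing
#' correction (mirroring percentage scoring as commonly configured).
#'
#' @param windows Output of [extract_windows()].
#' @param background Named percentage vector over the 20 residues (sums to
#'   100); default [aa_background()].
#' @param alpha Significance level (default 0.05).
#' @return Tibble of class `specificity_matrix`: `position`, `residue`, `n`,
#'   `observed_pct`, `background_pct`, `difference`, `z`, `p_value`,
#'   `significant`.
#' @export
positional_enrichment <- function(windows, background = aa_background(),
                                  alpha = 0.05) {
  if (nrow(windows) == 0) abort("no windows supplied")
  if (!all(AA20 %in% names(background)))
    abort("`background` must name all 20 canonical residues")
  background <- background[AA20]
  if (abs(sum(background) - 100) > 0.5)
    abort("`background` percentages must sum to 100")
  background <- 100 * background / sum(background)
  counts <- windows |>
    filter(.data$residue != TERMINUS) |>
    dplyr::count(.data$position, .data$residue)
  grid <- tidyr::expand_grid(
    position = factor(levels(windows$position), levels = levels(windows$position)),
    residue = AA20)
  out <- grid |>
    left_join(counts, by = c("position", "residue")) |>
    mutate(count = dplyr::coalesce(.data$n, 0L)) |>
    select(-"n") |>
    group_by(.data$position) |>
    mutate(n = sum(.data$count)) |>
    ungroup() |>
    mutate(
      observed_pct = if_else(.data$n > 0, 100 * .data$count / .data$n, NA_real_),
      background_pct = unname(background[.data$residue]),
      difference = .data$observed_pct - .data$background_pct,
      p0 = .data$background_pct / 100,
      z = if_else(.data$p0 > 0 & .data$p0 < 1,
                  (.data$count - .data$n * .data$p0) /
                    sqrt(.data$n * .data$p0 * (1 - .data$p0)),
                  NA_real_),
      p_value = 2 * pnorm(-abs(.data$z)),
      significant = .data$n > 0 & !is.na(.data$p_value) &
        .data$p_value < alpha) |>
    select(-"p0")
  attr(out, "alpha") <- alpha
  class(out) <- c("specificity_matrix", class(out))
  out
}

#' Per-position consensus of significant residue preferences
#'
#' For each window position, the significantly enriched residues sorted by
#' descending percentage difference, truncated to the top `top_k`.
#'
#' @param matrix A `specificity_matrix`.
#' @param top_k Residues to keep per position (default 3); 0 gives an empty
#'   report.
#' @return Tibble `position`, `rank`, `residue`, `difference`.
#' @export
consensus_report <- function(matrix, top_k = 3) {
  out <- matrix |>
    as_tibble() |>
    filter(.data$significant, .data$difference > 0) |>
    group_by(.data$position) |>
    arrange(desc(.data$difference), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    filter(.data$rank <= top_k) |>
    select("position", "rank", "residue", "difference")
  out
}

#' Logo-style enrichment plot
#'
#' Percentage-difference bars per position, significant residues labelled —
#' a plain-ggplot rendering of the positional specificity profile.
#'
#' @param object A `specificity_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.specificity_matrix <- function(object, ...) {
  dat <- filter(as_tibble(object), .data$significant)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$difference)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$difference > 0),
                      position = "stack", width = 0.8, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue),
                       position = ggplot2::position_stack(vjust = 0.5), size = 3) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f0e")) +
    ggplot2::labs(x = NULL, y = "observed - background (%)") +
    ggplot2::theme_minimal()
}
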