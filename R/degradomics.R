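#' Collapse duplicate peptide observations
#'
#' One quantification record per unique (peptide, preceding, following)
#' combination; per-condition abundances are summed across duplicate rows
#' (e.g. charge states or repeated identifications). Abundances at or below
#' `zero_floor` count as not detected and become `NA`.
#'
#' @param observations Tibble with `peptide`, `preceding`, `following`,
#'   `abundance_active`, `abundance_control` (`NA` = absent).
#' @param zero_floor Detection floor; abundances `<=` this are treated as
#'   absent (default 0).
#' @return Aggregated tibble, one row per unique peptide context.
#' @export
aggregate_observations <- function(observations, zero_floor = 0) {
  need <- c("peptide", "preceding", "following",
            "abundance_active", "abundance_control")
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols))
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (nrow(observations) == 0) return(as_tibble(observations[need]))
  observations |>
    mutate(peptide = toupper(.data$peptide)) |>
    group_by(.data$peptide, .data$preceding, .data$following) |>
    summarise(
      abundance_active = sum(.data$abundance_active, na.rm = TRUE),
      abundance_control = sum(.data$abundance_control, na.rm = TRUE),
      .groups = "drop") |>
    mutate(
      abundance_active = if_else(.data$abundance_active <= zero_floor,
                                 NA_real_, .data$abundance_active),
      abundance_control = if_else(.data$abundance_control <= zero_floor,
                                  NA_real_, .data$abundance_control))
}

#' Active/control abundance ratios with the singleton convention
#'
#' For peptides detected in both conditions the ratio is
#' `abundance_active / abundance_control`. Peptides detected in only one
#' condition (singletons) receive the fixed arbitrary ratio 100 on their
#' directed scale: active-only peptides get `ratio = 100` (log2 = 6.64) on the
#' active/control scale, control-only peptides get `conv_ratio = 100` on the
#' converse control/active scale. Both directed scales are computed in one
#' pass; the converse scale carries the evidence for peptide depletion by the
#' active enzyme (spanning tryptic corroboration).
#'
#' @param quants Aggregated quantifications from [aggregate_observations()].
#' @param singleton_ratio The arbitrary singleton ratio (default 100).
#' @return Tibble with `detection_class` (`both`/`active_only`/`control_only`),
#'   `ratio`, `log2_ratio`, `conv_ratio`, `conv_log2_ratio`. Rows with neither
#'   abundance present are dropped with a warning.
#' @export
compute_ratios <- function(quants, singleton_ratio = 100) {
  empty <- is.na(quants$abundance_active) & is.na(quants$abundance_control)
  if (any(empty)) {
    warn(sprintf("%d record(s) with no abundance in either condition dropped",
                 sum(empty)))
    quants <- quants[!empty, , drop = FALSE]
  }
  quants |>
    mutate(
      detection_class = dplyr::case_when(
        !is.na(.data$abundance_active) & !is.na(.data$abundance_control) ~ "both",
        !is.na(.data$abundance_active) ~ "active_only",
        TRUE ~ "control_only"),
      ratio = dplyr::case_when(
        .data$detection_class == "both" ~ .data$abundance_active / .data$abundance_control,
        .data$detection_class == "active_only" ~ singleton_ratio,
        TRUE ~ NA_real_),
      log2_ratio = log2(.data$ratio),
      conv_ratio = dplyr::case_when(
        .data$detection_class == "both" ~ .data$abundance_control / .data$abundance_active,
        .data$detection_class == "control_only" ~ singleton_ratio,
        TRUE ~ NA_real_),
      conv_log2_ratio = log2(.data$conv_ratio))
}

#' z-scores against the both-group ratio distribution
#'
#' The mean and standard deviation are estimated from the log2 ratios of
#' peptides detected in *both* conditions only; a z-score is then assigned to
#' every record, including singletons sitting at log2(100). Both directed
#' scales get their own scale statistics (for the converse scale these are the
#' negated both-group log2 ratios plus the control-only singletons at
#' log2(100)).
#'
#' @param records Output of [compute_ratios()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Input with `z` and `conv_z`; scale statistics are stored in
#'   attribute `"scale_stats"`.
#' @export
compute_zscores <- function(records, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  both <- records$log2_ratio[records$detection_class == "both"]
  if (length(both) < 2)
    abort("need >= 2 both-group peptides to estimate the ratio distribution")
  psd <- function(x) {
    s <- sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    s
  }
  m <- mean(both); s <- psd(both)
  if (s == 0) abort("degenerate ratio distribution: both-group sd is zero")
  m_conv <- -m                       # converse scale: log2 ratios negate
  out <- records |>
    mutate(z = (.data$log2_ratio - m) / s,
           conv_z = (.data$conv_log2_ratio - m_conv) / s)
  attr(out, "scale_stats") <- tibble(
    scale = c("active_over_control", "control_over_active"),
    mean_log2 = c(m, m_conv), sd_log2 = c(s, s),
    n_both = length(both), sd_type = sd_type)
  out
}

#' Select candidate cleavage-evidence peptides
#'
#' All active-only semi-tryptic singletons (selected regardless of z
#' magnitude) plus both-group semi-tryptic peptides with `z` strictly above
#' the threshold. Records with both termini non-tryptic are excluded and
#' returned in attribute `"flagged_nontryptic"`; semi-tryptic peptides
#' enriched on the control side (control-only, or converse z above threshold)
#' are returned in attribute `"unexplained_control"` — reported, never
#' suppressed, since their origin is unexplained by the active protease.
#'
#' @param records Output of [compute_zscores()]; must carry `tryptic_status`
#'   (see [classify_termini()]).
#' @param z_threshold Significance threshold, strict inequality (default 2).
#' @return Tibble of selected candidate records.
#' @export
select_candidates <- function(records, z_threshold = 2) {
  if (!"tryptic_status" %in% names(records))
    records <- classify_termini(records)
  semi <- filter(records, .data$tryptic_status == "semi")
  sel <- filter(semi,
    .data$detection_class == "active_only" |
      (.data$detection_class == "both" & .data$z > z_threshold))
  attr(sel, "flagged_nontryptic") <- filter(records, .data$tryptic_status == "non")
  attr(sel, "unexplained_control") <- filter(semi,
    .data$detection_class == "control_only" |
      (.data$detection_class == "both" & .data$conv_z > z_threshold))
  sel
}

# localize one peptide, warn on duplicates, return first span (or NULL)
localize_first <- function(protein, peptide, preceding, following) {
  spans <- locate_peptide(protein, peptide)
  if (nrow(spans) == 0) return(NULL)
  ok <- spans$preceding == preceding & spans$following == following
  if (any(ok)) spans <- spans[ok, , drop = FALSE]
  if (nrow(spans) > 1)
    warn(sprintf("peptide %s matches at %s; using first occurrence",
                 peptide, paste(spans$start, collapse = ", ")))
  spans[1, , drop = FALSE]
}

#' Call P1-P1' cleavage sites from candidate semi-tryptic peptides
#'
#' Each candidate's non-tryptic terminus defines a scissile-bond boundary: a
#' non-tryptic N-terminus at start s implies the site (s-1, s); a non-tryptic
#' C-terminus at end e implies (e, e+1). Candidates that fail to localize on
#' the substrate are skipped with a warning; fully tryptic candidates and
#' boundaries at a protein terminus are rejected. Duplicate boundaries merge
#' into a single site accumulating all supporting peptides. Sites are sorted
#' by position; peptides within a site by descending ratio then sequence.
#'
#' @param candidates Output of [select_candidates()] (or any classified record
#'   tibble with ratios/z).
#' @param protein Substrate (see [locate_peptide()]).
#' @param regions Optional tibble (`region`, `start`, `end`) used to annotate
#'   each site with a region label.
#' @return Tibble of class `site_calls`: `accession`, `p1_pos`, `p1`,
#'   `p1prime`, `region`, `n_semi`, `max_z`, `evidence` (list column of
#'   supporting records with span coordinates).
#' @export
call_cleavage_sites <- function(candidates, protein, regions = NULL) {
  pr <- as_protein(protein)
  L <- nchar(pr$sequence)
  if (!"tryptic_status" %in% names(candidates))
    candidates <- classify_termini(candidates)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    if (cand$tryptic_status == "fully") next      # not cleavage evidence
    sp <- localize_first(pr, cand$peptide, cand$preceding, cand$following)
    if (is.null(sp)) {
      warn(paste0("candidate peptide not found in substrate: ", cand$peptide))
      next
    }
    # a semi-tryptic peptide has exactly one non-tryptic terminus; re-derive
    # the termini from the localized span so boundary and context agree
    cl <- classify_termini(sp)
    for (side in c("n", "c")) {
      status <- if (side == "n") cl$n_term else cl$c_term
      if (status != "nontryptic") next
      p1 <- if (side == "n") sp$start - 1L else sp$end
      if (p1 < 1L || p1 + 1L > L) next            # protein terminus: rejected
      rows[[length(rows) + 1]] <- mutate(cand,
        p1_pos = p1, start = sp$start, end = sp$end, boundary_side = side)
    }
  }
  if (!length(rows)) {
    empty <- tibble(accession = character(), p1_pos = integer(),
                    p1 = character(), p1prime = character(),
                    region = character(), n_semi = numeric(),
                    max_z = numeric(), evidence = list())
    class(empty) <- c("site_calls", class(empty))
    return(empty)
  }
  ev <- bind_rows(rows)
  sites <- ev |>
    arrange(.data$p1_pos, desc(.data$ratio), .data$peptide) |>
    tidyr::nest(.by = "p1_pos", .key = "evidence") |>
    mutate(
      accession = pr$accession,
      p1 = substring(pr$sequence, .data$p1_pos, .data$p1_pos),
      p1prime = substring(pr$sequence, .data$p1_pos + 1L, .data$p1_pos + 1L),
      n_semi = map_dbl(.data$evidence, nrow),
      max_z = map_dbl(.data$evidence, ~suppressWarnings(max(.x$z, na.rm = TRUE)))) |>
    arrange(.data$p1_pos) |>
    select("accession", "p1_pos", "p1", "p1prime", "n_semi", "max_z", "evidence")
  sites$region <- annotate_region(sites$p1_pos, regions)
  sites <- select(sites, "accession", "p1_pos", "p1", "p1prime", "region",
                  dplyr::everything())
  class(sites) <- c("site_calls", class(sites))
  sites
}

annotate_region <- function(pos, regions) {
  if (is.null(regions)) return(rep(NA_character_, length(pos)))
  map_chr(pos, function(p) {
    hit <- regions$region[regions$start <= p & p <= regions$end]
    if (length(hit)) hit[1] else NA_character_
  })
}

#' Attach spanning tryptic evidence to called sites
#'
#' For each site, every fully tryptic record whose localized span *strictly*
#' contains the P1-P1' boundary (start <= P1 and end >= P1') is attached; a
#' peptide ending exactly at P1 does not span. A spanning peptide is marked
#' `corroborating` when it is control-only or its converse (control/active)
#' z-score exceeds the threshold — depletion of the intact tryptic peptide by
#' the active enzyme is converse evidence for cleavage at the site.
#'
#' @param sites A `site_calls` tibble from [call_cleavage_sites()].
#' @param records Full record tibble (with ratios, z, `tryptic_status`).
#' @param protein Substrate.
#' @param z_threshold Converse-scale significance threshold (default 2).
#' @return `sites` with list column `spanning` and counts `n_spanning`,
#'   `n_corroborating`.
#' @export
find_spanning_evidence <- function(sites, records, protein, z_threshold = 2) {
  pr <- as_protein(protein)
  if (!"tryptic_status" %in% names(records))
    records <- classify_termini(records)
  tryp <- filter(records, .data$tryptic_status == "fully")
  loc <- map(seq_len(nrow(tryp)), function(i)
    localize_first(pr, tryp$peptide[i], tryp$preceding[i], tryp$following[i]))
  keep <- !vapply(loc, is.null, logical(1))
  tryp <- tryp[keep, , drop = FALSE]
  loc <- bind_rows(loc[keep])
  if (nrow(tryp)) {
    tryp$start <- loc$start; tryp$end <- loc$end
  } else {
    tryp$start <- integer(); tryp$end <- integer()
  }
  out <- sites |>
    mutate(
      spanning = map(.data$p1_pos, function(p1) {
        sp <- filter(tryp, .data$start <= p1, .data$end >= p1 + 1L)
        mutate(sp, corroborating =
          .data$detection_class == "control_only" |
            (!is.na(.data$conv_z) & .data$conv_z > z_threshold)) |>
          arrange(desc(.data$conv_ratio), .data$peptide)
      }),
      n_spanning = map_dbl(.data$spanning, nrow),
      n_corroborating = map_dbl(.data$spanning, ~sum(.x$corroborating)))
  class(out) <- c("site_calls", setdiff(class(out), "site_calls"))
  out
}

#' Compare two cleavage-site sets
#'
#' Set operations on (accession, P1 position). Both inputs must refer to the
#' same substrate accession.
#'
#' @param a,b `site_calls` tibbles (or tibbles with `accession`, `p1_pos`).
#' @return List of tibbles `shared`, `only_a`, `only_b`, each sorted by
#'   position, with `p1`/`p1prime` labels carried from the corresponding
#'   input.
#' @export
compare_site_sets <- function(a, b) {
  acc <- union(unique(a$accession), unique(b$accession))
  if (length(acc) > 1)
    abort(paste0("site sets refer to different substrates: ",
                 paste(acc, collapse = " vs ")))
  key <- function(x) select(as_tibble(x), "accession", "p1_pos", "p1", "p1prime")
  ka <- key(a); kb <- key(b)
  list(
    shared = arrange(dplyr::semi_join(ka, kb, by = c("accession", "p1_pos")), .data$p1_pos),
    only_a = arrange(dplyr::anti_join(ka, kb, by = c("accession", "p1_pos")), .data$p1_pos),
    only_b = arrange(dplyr::anti_join(kb, ka, by = c("accession", "p1_pos")), .data$p1_pos))
}

#' Full cleavage-site calling pipeline
#'
#' Runs aggregation, ratio and z-score computation, terminus classification,
#' candidate selection, site calling and spanning-tryptic corroboration in
#' one call.
#'
#' @param observations Raw peptide observations (see [read_quant_table()]).
#' @param protein Substrate (see [locate_peptide()]).
#' @param z_threshold Significance threshold (default 2, strict).
#' @param proline_rule Trypsin proline rule (default `TRUE`).
#' @param sd_type `"sample"` or `"population"` standard deviation.
#' @param regions Optional region annotation table.
#' @param zero_floor Detection floor for abundances.
#' @return Object of class `degradome_calls`: list with `sites` (a
#'   `site_calls` tibble), `records`, `candidates`, `unexplained_control`,
#'   `flagged_nontryptic`, `scale_stats`, `params`.
#' @export
call_sites <- function(observations, protein, z_threshold = 2,
                       proline_rule = TRUE, sd_type = "sample",
                       regions = NULL, zero_floor = 0) {
  records <- observations |>
    aggregate_observations(zero_floor = zero_floor) |>
    compute_ratios() |>
    classify_termini(proline_rule = proline_rule) |>
    compute_zscores(sd_type = sd_type)
  cand <- select_candidates(records, z_threshold = z_threshold)
  sites <- call_cleavage_sites(cand, protein, regions = regions) |>
    find_spanning_evidence(records, protein, z_threshold = z_threshold)
  structure(list(
    sites = sites, records = records, candidates = cand,
    unexplained_control = attr(cand, "unexplained_control"),
    flagged_nontryptic = attr(cand, "flagged_nontryptic"),
    scale_stats = attr(records, "scale_stats"),
    params = list(z_threshold = z_threshold, proline_rule = proline_rule,
                  sd_type = sd_type, zero_floor = zero_floor)),
    class = "degradome_calls")
}

#' @export
print.degradome_calls <- function(x, ...) {
  cat("<degradome_calls>\n")
  cat(sprintf("  %d cleavage site(s) on %s from %d candidate peptide(s)\n",
              nrow(x$sites), x$sites$accession[1] %||% "?", nrow(x$candidates)))
  cat(sprintf("  z threshold > %g; %d record(s); %d unexplained control-enriched\n",
              x$params$z_threshold, nrow(x$records), nrow(x$unexplained_control)))
  invisible(x)
}

#' @rdname call_sites
#' @param x A `degradome_calls` object.
#' @param ... Unused.
#' @export
tidy.degradome_calls <- function(x, ...) {
  x$sites |>
    as_tibble() |>
    select("accession", "p1_pos", "p1", "p1prime", "region",
           "n_semi", "n_spanning", "n_corroborating", "max_z") |>
    mutate(site = paste0(.data$p1, .data$p1_pos, "-", .data$p1prime, .data$p1_pos + 1L),
           .after = "accession")
}

#' @rdname call_sites
#' @export
glance.degradome_calls <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_candidates = nrow(x$candidates),
    n_singletons = sum(x$candidates$detection_class == "active_only"),
    n_records = nrow(x$records),
    n_unexplained_control = nrow(x$unexplained_control),
    mean_log2 = x$scale_stats$mean_log2[1],
    sd_log2 = x$scale_stats$sd_log2[1])
}

#' Ratio/z-score overview plot for a degradome analysis
#'
#' Scatter of z-score against log2 abundance ratio for all records on the
#' active/control scale; candidate semi-tryptic peptides are highlighted and
#' the singleton convention (log2 ratio 6.64) shows as a vertical band.
#'
#' @param object A `degradome_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.degradome_calls <- function(object, ...) {
  rec <- mutate(object$records,
                candidate = paste(.data$peptide, .data$preceding, .data$following) %in%
                  paste(object$candidates$peptide, object$candidates$preceding,
                        object$candidates$following))
  rec <- filter(rec, !is.na(.data$z))
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$log2_ratio, y = .data$z)) +
    ggplot2::geom_hline(yintercept = object$params$z_threshold, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$candidate,
                                     shape = .data$tryptic_status), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 (active / control) abundance ratio", y = "z-score",
                  colour = "candidate", shape = "termini") +
    ggplot2::theme_minimal()
}
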