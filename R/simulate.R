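#' Generate a random substrate protein
#'
#' Residues are drawn from a background composition (default human
#' Swiss-Prot, [aa_background()]); at least one K/R is guaranteed in every
#' 30-residue stretch so tryptic digestion is never degenerate. Pure function
#' of (arguments, seed).
#'
#' @param length Protein length (>= 20).
#' @param seed Integer seed.
#' @param composition Optional named percentage vector over the 20 residues.
#' @param accession Accession for the record.
#' @return One-row tibble compatible with [read_fasta()] output.
#' @export
make_substrate <- function(length = 400, seed = 1, composition = NULL,
                           accession = "SYN_SUBSTRATE") {
  if (length < 20) abort("substrate length must be >= 20")
  composition <- composition %||% aa_background()
  composition <- composition[AA20]
  if (any(is.na(composition)) || any(composition < 0))
    abort("malformed composition")
  if (composition["K"] + composition["R"] <= 0)
    abort("infeasible composition: K and R both have zero weight")
  withr::with_seed(seed, {
    res <- sample(AA20, length, replace = TRUE, prob = composition)
    gap <- 0
    for (i in seq_len(length)) {
      gap <- if (res[i] %in% c("K", "R")) 0 else gap + 1
      if (gap >= 30) {
        res[i] <- sample(c("K", "R"), 1)
        gap <- 0
      }
    }
    tibble(accession = accession, description = "synthetic substrate",
           sequence = paste(res, collapse = ""), length = length, clean = TRUE)
  })
}

#' Simulate a paired active/control degradome quantification table
#'
#' Emulates the data-generating process behind paired active-enzyme /
#' inactive-control digest quantifications: fully tryptic background peptides
#' whose log2 active/control ratios are Normal(`noise_mean`, `noise_sd`);
#' injected cleavage events that, when detected, emit the semi-tryptic
#' product peptides on both sides of the scissile bond (active-only
#' singletons with probability `singleton_fraction`, otherwise both-group
#' with a large positive log2 shift); and site-spanning tryptic peptides
#' that drop out of the active digest (become control-only) with probability
#' `control_spanning_dropout`. Base intensity is cosmetic: only the ratio
#' structure matters to the caller.
#'
#' @param substrate Substrate tibble (default [make_substrate()] under the
#'   same seed).
#' @param sites Integer vector of injected P1 positions; default: `n_sites`
#'   positions sampled away from tryptic boundaries.
#' @param n_sites Number of injected sites when `sites` is `NULL`.
#' @param efficiency Per-site detection probability in \[0, 1\].
#' @param max_missed Missed-cleavage limit for the background digest.
#' @param noise_mean,noise_sd Both-group log2 ratio noise (defaults 0 and 2).
#' @param singleton_fraction Probability an enzyme-generated semi-tryptic
#'   peptide is active-only.
#' @param semi_log2_shift Log2 enrichment of non-singleton semi-tryptic
#'   products (default 6).
#' @param control_spanning_dropout Probability a site-spanning tryptic
#'   peptide becomes control-only.
#' @param base_intensity Cosmetic base LFQ intensity.
#' @param seed Integer seed; same seed, byte-identical output.
#' @return List of class `degradome_sim`: `quant` (observation tibble),
#'   `truth` (injected sites and generated evidence, versioned), `substrate`.
#' @export
simulate_degradome <- function(substrate = NULL, sites = NULL, n_sites = 5,
                               efficiency = 1, max_missed = 3,
                               noise_mean = 0, noise_sd = 2,
                               singleton_fraction = 0.9,
                               semi_log2_shift = 6,
                               control_spanning_dropout = 0.5,
                               base_intensity = 1e6, seed = 1) {
  stopifnot(efficiency >= 0, efficiency <= 1,
            singleton_fraction >= 0, singleton_fraction <= 1,
            control_spanning_dropout >= 0, control_spanning_dropout <= 1,
            noise_sd > 0)
  substrate <- substrate %||% make_substrate(seed = seed)
  pr <- as_protein(substrate)
  res <- strsplit(pr$sequence, "")[[1]]
  L <- length(res)
  dig0 <- tryptic_digest(substrate, max_missed = 0)
  withr::with_seed(seed + 1L, {
    if (is.null(sites)) {
      # candidate boundaries strictly inside a zero-missed peptide, away from
      # K/R so the products are genuinely semi-tryptic
      ok <- setdiff(15:(L - 15), which(res %in% c("K", "R")))
      ok <- ok[res[ok + 1] != "P" & !(res[ok + 1] %in% c("K", "R"))]
      if (length(ok) < n_sites) abort("substrate too short for n_sites")
      sites <- sort(sample(ok, n_sites))
    }
    if (any(sites <= 1 | sites >= L))
      abort("injected sites must be strictly inside the substrate")
    intensity <- function(n) rlnorm(n, meanlog = log(base_intensity), sdlog = 0.5)

    # (i) both-group fully tryptic background
    bg <- filter(tryptic_digest(substrate, max_missed = min(max_missed, 1)),
                 nchar(.data$peptide) >= 5, nchar(.data$peptide) <= 45)
    bg_ctrl <- intensity(nrow(bg))
    bg_quant <- tibble(
      peptide = bg$peptide, preceding = bg$preceding, following = bg$following,
      start = bg$start, end = bg$end,
      abundance_active = bg_ctrl * 2^rnorm(nrow(bg), noise_mean, noise_sd),
      abundance_control = bg_ctrl)

    # (ii) semi-tryptic products of injected cleavage events
    semi_rows <- list(); truth_rows <- list()
    for (p1 in sites) {
      detected <- runif(1) < efficiency
      n_emitted <- 0L
      if (detected) {
        host <- filter(dig0, .data$start <= p1, .data$end >= p1 + 1)
        products <- if (nrow(host) == 1) {
          bind_rows(
            tibble(start = host$start, end = p1),
            tibble(start = p1 + 1, end = host$end)) |>
            filter(.data$end - .data$start + 1 >= 4)
        } else tibble(start = integer(), end = integer())
        for (j in seq_len(nrow(products))) {
          s <- products$start[j]; e <- products$end[j]
          singleton <- runif(1) < singleton_fraction
          ctrl <- intensity(1)
          semi_rows[[length(semi_rows) + 1]] <- tibble(
            peptide = substring(pr$sequence, s, e),
            preceding = if (s == 1) TERMINUS else res[s - 1],
            following = if (e == L) TERMINUS else res[e + 1],
            abundance_active = ctrl *
              2^(semi_log2_shift + rnorm(1, 0, noise_sd / 2)),
            abundance_control = if (singleton) NA_real_ else ctrl)
          n_emitted <- n_emitted + 1L
        }
      }
      p1_res <- res[p1]; p1prime_res <- res[p1 + 1]
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        p1_pos = p1, p1 = p1_res, p1prime = p1prime_res,
        detected = detected, n_semi_emitted = n_emitted)
    }
    semi_quant <- if (length(semi_rows)) list_rbind(semi_rows) else
      tibble(peptide = character(), preceding = character(),
             following = character(), abundance_active = numeric(),
             abundance_control = numeric())

    # (iii) spanning tryptic dropout in the active digest
    for (p1 in sites) {
      spans <- which(bg_quant$start <= p1 & bg_quant$end >= p1 + 1)
      drop <- spans[runif(length(spans)) < control_spanning_dropout]
      bg_quant$abundance_active[drop] <- NA_real_
    }

    quant <- bind_rows(select(bg_quant, -"start", -"end"), semi_quant)
    truth <- list(version = "1.0",
                  sites = list_rbind(truth_rows),
                  params = list(n_sites = length(sites),
                                efficiency = efficiency,
                                noise_mean = noise_mean, noise_sd = noise_sd,
                                singleton_fraction = singleton_fraction,
                                semi_log2_shift = semi_log2_shift,
                                control_spanning_dropout = control_spanning_dropout,
                                seed = seed))
    structure(list(quant = quant, truth = truth, substrate = substrate),
              class = "degradome_sim")
  })
}

#' @export
print.degradome_sim <- function(x, ...) {
  cat(sprintf("<degradome_sim> %d observation(s), %d injected site(s) (%d detected)\n",
              nrow(x$quant), nrow(x$truth$sites), sum(x$truth$sites$detected)))
  invisible(x)
}

#' Simulate substrate-depletion progress curves
#'
#' Points from [progress_fraction()] plus Gaussian noise, clipped to
#' \[0, 1.05\]. Defaults follow a neoepitope-ELISA versicanase time course:
#' 5.5 nM enzyme, seven points over 0-20 min, three replicates, sd 0.02.
#'
#' @param kcat_km True catalytic efficiency (M-1 s-1).
#' @param enzyme_conc Enzyme concentration (molar).
#' @param times Time grid (seconds).
#' @param replicates Number of replicate curves.
#' @param noise_sd Gaussian noise sd on the fraction.
#' @param seed Integer seed.
#' @return Tibble `replicate`, `time_s`, `enzyme_conc`, `fraction`.
#' @export
simulate_progress_curves <- function(kcat_km = 2.4e5, enzyme_conc = 5.5e-9,
                                     times = seq(0, 1200, length.out = 7),
                                     replicates = 3, noise_sd = 0.02,
                                     seed = 1) {
  stopifnot(length(times) > 0, noise_sd >= 0)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(replicate = seq_len(replicates), time_s = times)
    truth <- progress_fraction(enzyme_conc, grid$time_s, kcat_km)
    grid |>
      mutate(enzyme_conc = enzyme_conc,
             fraction = pmin(pmax(truth + rnorm(n(), 0, noise_sd), 0), 1.05))
  })
}

#' Simulate a tight-binding inhibition series
#'
#' vi/v0 from [morrison_velocity()] plus Gaussian noise, clipped to
#' \[0, 1.05\]. The default titration clusters points around the enzyme
#' concentration, where a tight-binding series is most informative, within
#' a 0-8 nM inhibitor range at Et = 0.2 nM, in duplicate.
#'
#' @param ki True Ki(app) (molar).
#' @param Et Total active enzyme concentration (molar).
#' @param inhibitor_concs Inhibitor grid (molar); must include 0.
#' @param replicates Replicates per concentration.
#' @param noise_sd Gaussian noise sd on vi/v0.
#' @param seed Integer seed.
#' @return Tibble `replicate`, `inhibitor_conc`, `vi_over_v0`, with `Et`
#'   stored as an attribute.
#' @export
simulate_inhibition_series <- function(ki = 45e-12, Et = 0.2e-9,
                                       inhibitor_concs = c(0, 0.05, 0.1, 0.15,
                                                           0.2, 0.25, 0.3, 0.4,
                                                           0.5, 1, 2, 4, 8) * 1e-9,
                                       replicates = 2, noise_sd = 0.03,
                                       seed = 1) {
  if (!any(inhibitor_concs == 0)) abort("inhibitor grid must include 0")
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(replicate = seq_len(replicates),
                               inhibitor_conc = inhibitor_concs)
    truth <- morrison_velocity(Et, grid$inhibitor_conc, ki)
    out <- mutate(grid,
                  vi_over_v0 = pmin(pmax(truth + rnorm(n(), 0, noise_sd), 0), 1.05))
    attr(out, "Et") <- Et
    out
  })
}
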