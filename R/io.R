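DEFAULT_QUANT_COLS <- c(peptide = "peptide", preceding = "preceding",
                        following = "following",
                        abundance_active = "abundance_active",
                        abundance_control = "abundance_control")

#' Read a peptide quantification table
#'
#' Reads a TSV (or CSV, sniffed from the extension / first line) of peptide
#' observations with configurable header names. Rows failing validation
#' (negative or unparseable abundance, empty peptide) are dropped and reported
#' with their line numbers.
#'
#' @param path Delimited text file.
#' @param mapping Named character vector mapping the canonical names
#'   (`peptide`, `preceding`, `following`, `abundance_active`,
#'   `abundance_control`) to the file's header names; unmentioned names map
#'   to themselves.
#' @param delim Field delimiter; default sniffed (`"\t"` or `","`).
#' @return Tibble of validated observations (absent abundances are `NA`).
#' @export
read_quant_table <- function(path, mapping = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("quant table not found: ", path))
  map_full <- DEFAULT_QUANT_COLS
  if (!is.null(mapping)) map_full[names(mapping)] <- unname(mapping)
  if (is.null(delim)) {
    first <- readLines(path, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing_cols <- setdiff(unname(map_full), names(raw))
  if (length(missing_cols))
    abort(paste0("quant table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  df <- tibble(
    peptide = toupper(raw[[map_full["peptide"]]]),
    preceding = raw[[map_full["preceding"]]],
    following = raw[[map_full["following"]]],
    abundance_active = suppressWarnings(as.numeric(raw[[map_full["abundance_active"]]])),
    abundance_control = suppressWarnings(as.numeric(raw[[map_full["abundance_control"]]])))
  raw_act <- raw[[map_full["abundance_active"]]]
  raw_ctl <- raw[[map_full["abundance_control"]]]
  bad_parse <- (!is.na(raw_act) & raw_act != "" & is.na(df$abundance_active)) |
    (!is.na(raw_ctl) & raw_ctl != "" & is.na(df$abundance_control))
  bad_neg <- (!is.na(df$abundance_active) & df$abundance_active < 0) |
    (!is.na(df$abundance_control) & df$abundance_control < 0)
  bad_pep <- is.na(df$peptide) | df$peptide == "" |
    grepl(paste0("[^", paste(AA20, collapse = ""), "]"), df$peptide)
  bad <- bad_parse | bad_neg | bad_pep
  if (any(bad)) {
    # +1 for the header line
    warn(paste0(sum(bad), " row(s) rejected (line ",
                paste(which(bad) + 1L, collapse = ", "), "): ",
                "negative/unparseable abundance or invalid peptide"))
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Write (and read back) a cleavage-site report
#'
#' Writes a deterministic site report as TSV (one row per site: accession,
#' P1 position and residues, region, evidence counts, max z) and/or JSON
#' (full nested evidence). `read_site_report()` round-trips either format
#' back to a site table.
#'
#' @param calls A `degradome_calls` object or `site_calls` tibble.
#' @param path Output path without extension; `<path>.tsv` / `<path>.json`
#'   are written.
#' @param formats Subset of `c("tsv", "json")`.
#' @return Invisibly, the written file paths.
#' @export
write_site_report <- function(calls, path, formats = c("tsv", "json")) {
  sites <- if (inherits(calls, "degradome_calls")) calls$sites else calls
  flat <- site_table(sites)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if ("tsv" %in% formats) {
    f <- paste0(path, ".tsv")
    readr::write_tsv(flat, f)
    written <- c(written, f)
  }
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    payload <- list(version = "1.0", sites = purrr::transpose(as.list(
      mutate(as_tibble(sites),
             evidence = map(.data$evidence, as_tibble),
             spanning = if ("spanning" %in% names(sites))
               map(.data$spanning, as_tibble) else NULL))))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, f)
  }
  invisible(written)
}

site_table <- function(sites) {
  out <- as_tibble(sites)
  out$n_spanning <- out$n_spanning %||% NA_real_
  out$n_corroborating <- out$n_corroborating %||% NA_real_
  out |>
    mutate(site = paste0(.data$p1, .data$p1_pos, "-", .data$p1prime,
                         .data$p1_pos + 1L)) |>
    select("accession", "site", "p1_pos", "p1", "p1prime", "region",
           "n_semi", "n_spanning", "n_corroborating", "max_z")
}

#' @rdname write_site_report
#' @export
read_site_report <- function(path) {
  if (grepl("\\.json$", path)) {
    payload <- jsonlite::read_json(path)
    rows <- map(payload$sites, function(s) tibble(
      accession = s$accession, p1_pos = as.integer(s$p1_pos),
      p1 = s$p1, p1prime = s$p1prime,
      region = s$region %||% NA_character_,
      n_semi = as.numeric(s$n_semi %||% NA),
      n_spanning = as.numeric(s$n_spanning %||% NA),
      n_corroborating = as.numeric(s$n_corroborating %||% NA),
      max_z = as.numeric(s$max_z %||% NA)))
    arrange(list_rbind(rows), .data$p1_pos)
  } else {
    readr::read_tsv(path, show_col_types = FALSE) |>
      arrange(.data$p1_pos)
  }
}
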