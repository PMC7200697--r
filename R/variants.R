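#' Filter configuration for substrain-private variant discovery
#'
#' Encodes the exome candidate filter: keep calls with no rsID, QUAL >= 70
#' (a call at exactly 70 is kept), homozygous-alt genotype, on a
#' whitelisted chromosome (X by default), with a protein-affecting
#' consequence; then remove calls present in the comparator substrain or in
#' more than `max_shared_panel_strains` panel strains.
#'
#' @param min_qual Minimum QUAL kept.
#' @param chrom_whitelist Chromosomes kept.
#' @param allowed_consequences Consequence classes kept.
#' @param max_shared_panel_strains A surviving call is removed if seen in
#'   more panel strains than this (default 0: any occurrence removes).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_qual = 70,
                          chrom_whitelist = "X",
                          allowed_consequences = c("nonsynonymous", "stop_gained",
                                                   "splice_donor", "splice_acceptor"),
                          max_shared_panel_strains = 0L) {
  if (min_qual < 0 || max_shared_panel_strains < 0) {
    abort("thresholds must be nonnegative")
  }
  if (!length(chrom_whitelist)) abort("chromosome whitelist must be non-empty")
  structure(list(min_qual = min_qual, chrom_whitelist = chrom_whitelist,
                 allowed_consequences = allowed_consequences,
                 max_shared_panel_strains = as.integer(max_shared_panel_strains)),
            class = "filter_config")
}

.bases <- c("A", "C", "G", "T")

#' Known substrain-private X-linked coding variants of BALB/cByJ
#'
#' The Gdi1 (X:74309969 C>T, R276C) and Irs4 (X:141723152 G>A, L683F)
#' coding variants private to BALB/cByJ — the default planted truth for the
#' synthetic panel generator.
#'
#' @return Tibble of planted-variant site specs.
#' @export
study_private_variants <- function() {
  tibble(chrom = "X", pos = c(74309969L, 141723152L),
         ref = c("C", "G"), alt = c("T", "A"),
         consequence = "nonsynonymous", gene = c("Gdi1", "Irs4"))
}

#' Generate a multi-strain variant panel with planted private variants
#'
#' Emits per-strain calls (chrom/pos/ref/alt/QUAL/genotype/rsID/consequence)
#' in which the planted variants are X-linked, homozygous-alt, novel (no
#' rsID), QUAL >= 70, protein-coding and present only in the focal strain,
#' hidden among decoys of the six removable classes: rsID-bearing, low
#' quality (QUAL < 70), heterozygous, autosomal, shared between the focal
#' pair, and shared with the wider strain panel (plus optional synonymous
#' decoys). Ground-truth labels are returned alongside.
#'
#' @param n_strains Total strains: focal, comparator, and `n_strains - 2`
#'   panel strains.
#' @param planted_private Site spec tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `consequence`); default [study_private_variants()].
#' @param decoy_mix Named counts over `rsid`, `low_qual`, `het`,
#'   `autosomal`, `shared_pair`, `shared_panel`, `synonymous`.
#' @param focal,comparator Strain labels.
#' @param seed Integer seed; generation is deterministic.
#' @return A list with `calls` (long tibble over strains) and `truth`
#'   (per-site labels with `planted` flag).
#' @export
generate_variant_panel <- function(n_strains = 8L,
                                   planted_private = study_private_variants(),
                                   decoy_mix = c(rsid = 40L, low_qual = 40L,
                                                 het = 40L, autosomal = 40L,
                                                 shared_pair = 40L,
                                                 shared_panel = 40L,
                                                 synonymous = 10L),
                                   focal = "BALB_cByJ", comparator = "BALB_cJ",
                                   seed = 1L) {
  if (n_strains < 2) abort("need at least focal and comparator strains")
  classes <- c("rsid", "low_qual", "het", "autosomal", "shared_pair",
               "shared_panel", "synonymous")
  decoy_mix <- decoy_mix[intersect(names(decoy_mix), classes)]
  panel_strains <- if (n_strains > 2) paste0("PANEL_", seq_len(n_strains - 2L)) else character()
  n_shared_panel <- if ("shared_panel" %in% names(decoy_mix))
    decoy_mix[["shared_panel"]] else 0L
  if (!is.na(n_shared_panel) && n_shared_panel > 0 && !length(panel_strains)) {
    abort("shared_panel decoys need at least one panel strain (n_strains >= 3)")
  }
  with_seed(derive_seed(seed, "variants"), {
    n_decoy <- sum(decoy_mix)
    # draw decoy sites avoiding collisions with planted positions and each other
    draw_sites <- function(n, chroms) {
      pos <- integer(0); chrom <- character(0)
      while (length(pos) < n) {
        k <- n - length(pos)
        p <- sample.int(170e6, k)
        ch <- sample(chroms, k, replace = TRUE)
        key <- paste(ch, p)
        taken <- c(paste(chrom, pos), paste(planted_private$chrom, planted_private$pos))
        ok <- !key %in% taken & !duplicated(key)
        pos <- c(pos, p[ok]); chrom <- c(chrom, ch[ok])
      }
      tibble(chrom = chrom, pos = pos)
    }
    decoy_class <- rep(names(decoy_mix), decoy_mix)
    sites <- draw_sites(n_decoy, "X")
    auto_idx <- which(decoy_class == "autosomal")
    if (length(auto_idx)) {
      sites$chrom[auto_idx] <- sample(as.character(1:19), length(auto_idx),
                                      replace = TRUE)
    }
    ref <- sample(.bases, n_decoy, replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(.bases, .x), 1))
    decoys <- tibble(
      chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
      qual = round(runif(n_decoy, 70, 255), 1),
      genotype = "hom_alt",
      rsid = NA_character_,
      consequence = sample(c("nonsynonymous", "stop_gained", "splice_donor",
                             "splice_acceptor"), n_decoy, replace = TRUE),
      decoy_class = decoy_class
    )
    decoys$rsid[decoy_class == "rsid"] <-
      paste0("rs", sample.int(1e8, sum(decoy_class == "rsid")))
    decoys$qual[decoy_class == "low_qual"] <-
      round(runif(sum(decoy_class == "low_qual"), 1, 69.9), 1)
    decoys$genotype[decoy_class == "het"] <- "het"
    decoys$consequence[decoy_class == "synonymous"] <- "synonymous"

    planted <- dplyr::mutate(planted_private,
                             qual = round(runif(dplyr::n(), 70, 255), 1),
                             genotype = "hom_alt", rsid = NA_character_,
                             decoy_class = NA_character_)
    focal_calls <- dplyr::bind_rows(
      dplyr::select(planted, "chrom", "pos", "ref", "alt", "qual",
                    "genotype", "rsid", "consequence", "decoy_class"),
      decoys
    ) |> dplyr::mutate(strain = focal)

    comp_calls <- focal_calls |>
      dplyr::filter(.data$decoy_class %in% "shared_pair") |>
      dplyr::mutate(strain = comparator)
    panel_calls <- focal_calls |>
      dplyr::filter(.data$decoy_class %in% "shared_panel") |>
      (\(d) {
        if (nrow(d) == 0) return(d[0, ])
        purrr::map(seq_len(nrow(d)), function(i) {
          who <- sample(panel_strains, sample.int(length(panel_strains), 1))
          dplyr::mutate(d[rep(i, length(who)), ], strain = who)
        }) |> dplyr::bind_rows()
      })()
    calls <- dplyr::bind_rows(focal_calls, comp_calls, panel_calls) |>
      dplyr::arrange(.data$strain, .data$chrom, .data$pos) |>
      dplyr::select("strain", "chrom", "pos", "ref", "alt", "qual",
                    "genotype", "rsid", "consequence")
    truth <- focal_calls |>
      dplyr::mutate(planted = is.na(.data$decoy_class)) |>
      dplyr::select("chrom", "pos", "ref", "alt", "planted", "decoy_class") |>
      dplyr::arrange(.data$chrom, .data$pos)
    list(calls = calls, truth = truth,
         strains = c(focal = focal, comparator = comparator,
                     setNames(panel_strains, rep("panel", length(panel_strains)))))
  })
}

#' Apply the single-strain candidate filter
#'
#' A call survives iff it has no rsID, QUAL >= `min_qual`, a
#' homozygous-alt genotype, sits on a whitelisted chromosome, and carries an
#' allowed consequence. Removals are tallied per rule in the fixed order
#' rsID, quality, zygosity, chromosome, consequence; calls with a missing
#' genotype are excluded up front and counted as malformed. The final
#' survivor set is the same under any rule order (the rules commute); only
#' the tally depends on the order.
#'
#' @param calls Tibble of calls from one strain (`chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `genotype`, `rsid`, `consequence`).
#' @param cfg A [filter_config()].
#' @return A list of class `variant_filter`: `candidates` (survivors) and
#'   `tally` (per-rule removal waterfall).
#' @export
filter_focal_strain <- function(calls, cfg = filter_config()) {
  if ("strain" %in% names(calls) && dplyr::n_distinct(calls$strain) > 1) {
    abort("`calls` must come from a single strain")
  }
  n0 <- nrow(calls)
  malformed <- is.na(calls$genotype)
  calls <- calls[!malformed, ]
  steps <- list(
    rsID = function(d) is.na(d$rsid) | d$rsid == ".",
    quality = function(d) d$qual >= cfg$min_qual,
    zygosity = function(d) d$genotype == "hom_alt",
    chromosome = function(d) d$chrom %in% cfg$chrom_whitelist,
    consequence = function(d) d$consequence %in% cfg$allowed_consequences
  )
  tally <- tibble(rule = c("malformed", names(steps)),
                  removed = c(sum(malformed), rep(0L, length(steps))),
                  remaining = c(n0 - sum(malformed), rep(0L, length(steps))))
  for (i in seq_along(steps)) {
    keep <- steps[[i]](calls)
    tally$removed[i + 1] <- sum(!keep)
    calls <- calls[keep, ]
    tally$remaining[i + 1] <- nrow(calls)
  }
  structure(list(candidates = calls, tally = tally), class = "variant_filter")
}

call_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")

#' Remove calls shared with the comparator substrain or the strain panel
#'
#' Sharing is keyed on (chrom, pos, ref, alt). A survivor is removed if the
#' comparator carries the same call, or if more than
#' `max_shared_panel_strains` panel strains do. Duplicate keys within one
#' strain are deduplicated with a warning. Output is sorted by position.
#'
#' @param focal A `variant_filter` result or a tibble of focal survivors.
#' @param comparator Tibble of comparator-strain calls.
#' @param panel Tibble of panel calls with a `strain` column (may be empty).
#' @param cfg A [filter_config()].
#' @return A `variant_filter` with the subtraction steps appended to the
#'   tally.
#' @export
subtract_shared <- function(focal, comparator, panel = NULL,
                            cfg = filter_config()) {
  res <- if (inherits(focal, "variant_filter")) focal
         else list(candidates = focal,
                   tally = tibble(rule = character(), removed = integer(),
                                  remaining = integer()))
  surv <- res$candidates
  if (anyDuplicated(call_key(surv))) {
    warn("duplicate call keys within the focal strain; deduplicating")
    surv <- surv[!duplicated(call_key(surv)), ]
  }
  comp_keys <- unique(call_key(comparator))
  keep <- !call_key(surv) %in% comp_keys
  n_comp <- sum(!keep)
  surv <- surv[keep, ]
  n_panel <- 0L
  if (!is.null(panel) && nrow(panel)) {
    shared_counts <- panel |>
      dplyr::distinct(.data$strain, .data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::count(.data$chrom, .data$pos, .data$ref, .data$alt, name = "n_strains")
    over <- shared_counts[shared_counts$n_strains > cfg$max_shared_panel_strains, ]
    keep <- !call_key(surv) %in% call_key(over)
    n_panel <- sum(!keep)
    surv <- surv[keep, ]
  }
  surv <- dplyr::arrange(surv, .data$chrom, .data$pos)
  tally <- dplyr::bind_rows(
    res$tally,
    tibble(rule = c("shared_comparator", "shared_panel"),
           removed = c(n_comp, n_panel),
           remaining = c(nrow(res$candidates) - n_comp, nrow(surv)))
  )
  structure(list(candidates = surv, tally = tally), class = "variant_filter")
}

#' @export
print.variant_filter <- function(x, ...) {
  cat("<variant_filter> ", nrow(x$candidates), " candidate(s)\n", sep = "")
  print(x$tally)
  invisible(x)
}

#' Structured report of a variant-filter run
#'
#' @param result A `variant_filter` (after [subtract_shared()]).
#' @param json_path,text_path Optional output paths.
#' @return A list with `candidates`, `waterfall` and `text` (human-readable
#'   lines); written as JSON/text if paths are given. Deterministic for
#'   identical input.
#' @export
pipeline_report <- function(result, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(result, "variant_filter"))
  cand <- result$candidates
  text <- c(
    "Substrain-private variant filter",
    sprintf("rule %-18s removed %6d remaining %6d",
            result$tally$rule, result$tally$removed, result$tally$remaining),
    if (nrow(cand) == 0) "candidates: none" else c(
      "candidates:",
      sprintf("  %s:%d %s>%s QUAL=%s %s %s", cand$chrom, cand$pos, cand$ref,
              cand$alt, format(cand$qual), cand$genotype, cand$consequence))
  )
  report <- list(n_candidates = nrow(cand),
                 waterfall = result$tally,
                 candidates = cand,
                 text = text)
  if (!is.null(json_path)) {
    jsonlite::write_json(report[c("n_candidates", "waterfall", "candidates")],
                         json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(text_path)) writeLines(text, text_path)
  report
}
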