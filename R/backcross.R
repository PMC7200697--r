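#' Mouse-like genetic map for backcross simulation
#'
#' Nineteen autosomes plus X with genetic lengths in centimorgans. Meioses
#' follow a Haldane model: crossover counts are Poisson with mean
#' length/100, positions uniform, no interference. The default lengths are
#' generic mouse-scale values and are fully overridable.
#'
#' @param autosome_cm Numeric vector of 19 autosome lengths (cM).
#' @param x_cm X chromosome length (cM).
#' @return An object of class `genome_model` (tibble of `chrom`,
#'   `length_cm`).
#' @export
genome_model <- function(autosome_cm = c(98, 92, 80, 84, 92, 79, 89, 76, 75,
                                         78, 88, 64, 67, 66, 59, 57, 61, 59, 39),
                         x_cm = 80) {
  if (length(autosome_cm) != 19 || any(autosome_cm <= 0) || x_cm <= 0) {
    abort("need 19 positive autosome lengths and a positive X length")
  }
  structure(tibble(chrom = c(as.character(1:19), "X"),
                   length_cm = c(autosome_cm, x_cm)),
            class = c("genome_model", "tbl_df", "tbl", "data.frame"))
}

# Haplotypes are run-length maps: list(breaks = segment end positions (cM,
# last == chromosome length), origin = integer per segment (1 = donor,
# 2 = recurrent)).
new_hap <- function(L, origin) list(breaks = L, origin = origin)

hap_at <- function(hap, pos) hap$origin[findInterval(pos, hap$breaks,
                                                     left.open = TRUE) + 1L]

# One meiosis over a chromosome pair: Poisson(L/100) crossovers at uniform
# positions, random start phase. The gamete is read off a refined partition
# of [0, L] (crossovers plus both parental breakpoints); adjacent segments of
# equal origin are merged.
meiose <- function(h1, h2, L) {
  n_x <- rpois(1, L / 100)
  start_h1 <- runif(1) < 0.5
  if (n_x == 0) return(if (start_h1) h1 else h2)
  xs <- sort(runif(n_x, 0, L))
  cuts <- sort(unique(c(xs, h1$breaks, h2$breaks)))
  mids <- (c(0, head(cuts, -1)) + cuts) / 2
  on_h1 <- start_h1 == (findInterval(mids, xs) %% 2 == 0)
  origin <- ifelse(on_h1, hap_at(h1, mids), hap_at(h2, mids))
  keep <- c(origin[-1] != origin[-length(origin)], TRUE)
  list(breaks = cuts[keep], origin = origin[keep])
}

# individuals: list(sex, autosomes = list of chr -> list(h1, h2),
#                   X = list of 1 (male) or 2 (female) haplotypes)
founder <- function(genome, origin, sex) {
  auto_len <- genome$length_cm[genome$chrom != "X"]
  x_len <- genome$length_cm[genome$chrom == "X"]
  list(sex = sex,
       autosomes = purrr::map(auto_len, ~ list(new_hap(.x, origin),
                                               new_hap(.x, origin))),
       X = if (sex == "male") list(new_hap(x_len, origin))
           else list(new_hap(x_len, origin), new_hap(x_len, origin)))
}

cross_individuals <- function(mother, father, sex, genome) {
  auto_len <- genome$length_cm[genome$chrom != "X"]
  x_len <- genome$length_cm[genome$chrom == "X"]
  autosomes <- purrr::map(seq_along(auto_len), function(i) {
    list(meiose(mother$autosomes[[i]][[1]], mother$autosomes[[i]][[2]], auto_len[i]),
         meiose(father$autosomes[[i]][[1]], father$autosomes[[i]][[2]], auto_len[i]))
  })
  mat_x <- meiose(mother$X[[1]], mother$X[[2]], x_len)
  X <- if (sex == "male") list(mat_x) else list(mat_x, father$X[[1]])
  list(sex = sex, autosomes = autosomes, X = X)
}

# length-weighted genotype fractions over autosomes + X; the single male X
# counts hemizygous segments as homozygous for their origin
genotype_fractions <- function(ind, genome) {
  pair_lengths <- function(h1, h2) {
    cuts <- sort(unique(c(h1$breaks, h2$breaks)))
    widths <- diff(c(0, cuts))
    mids <- cuts - widths / 2
    o1 <- hap_at(h1, mids); o2 <- hap_at(h2, mids)
    c(het = sum(widths[o1 != o2]),
      hom_donor = sum(widths[o1 == 1 & o2 == 1]),
      hom_rec = sum(widths[o1 == 2 & o2 == 2]),
      donor_alleles = sum(widths * ((o1 == 1) + (o2 == 1)) / 2))
  }
  auto <- Reduce(`+`, purrr::map(ind$autosomes, ~ pair_lengths(.x[[1]], .x[[2]])))
  auto_total <- sum(genome$length_cm[genome$chrom != "X"])
  x_len <- genome$length_cm[genome$chrom == "X"]
  if (length(ind$X) == 1) {
    h <- ind$X[[1]]
    widths <- diff(c(0, h$breaks))
    xx <- c(het = 0,
            hom_donor = sum(widths[h$origin == 1]),
            hom_rec = sum(widths[h$origin == 2]),
            donor_alleles = sum(widths[h$origin == 1]))
  } else {
    xx <- pair_lengths(ind$X[[1]], ind$X[[2]])
  }
  total <- auto_total + x_len
  tibble(
    het_frac = (auto[["het"]] + xx[["het"]]) / total,
    hom_recurrent_frac = (auto[["hom_rec"]] + xx[["hom_rec"]]) / total,
    donor_frac = (auto[["donor_alleles"]] + xx[["donor_alleles"]]) / total,
    het_frac_autosomal = auto[["het"]] / auto_total,
    donor_frac_autosomal = auto[["donor_alleles"]] / auto_total,
    donor_frac_x = xx[["donor_alleles"]] / x_len
  )
}

# contiguous heterozygous tract length (cM) around a position on the X
het_tract_around <- function(ind, pos) {
  if (length(ind$X) == 1) return(0)
  h1 <- ind$X[[1]]; h2 <- ind$X[[2]]
  cuts <- sort(unique(c(h1$breaks, h2$breaks)))
  starts <- c(0, head(cuts, -1))
  mids <- (starts + cuts) / 2
  het <- hap_at(h1, mids) != hap_at(h2, mids)
  i <- findInterval(pos, cuts, left.open = TRUE) + 1L
  if (!het[i]) return(0)
  lo <- i; while (lo > 1 && het[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(het) && het[hi + 1]) hi <- hi + 1
  cuts[hi] - starts[lo]
}

#' Describe a marker-selected backcross breeding scheme
#'
#' The study scheme: an F1 female (donor x recurrent) is backcrossed to
#' recurrent males for `n_backcross` generations, selecting at each
#' generation a daughter heterozygous at a single X-linked marker; a final
#' cross then produces the terminal cohort (males by default), in which the
#' selected marker segregates freely.
#'
#' @param n_backcross Number of marker-selected backcross generations.
#' @param marker_pos_cm X-chromosome marker position (cM); `NULL` disables
#'   selection.
#' @param final_cross Add one last unselected cross to the recurrent parent?
#' @param terminal_sex Sex of the terminal animal.
#' @return An object of class `breeding_scheme`.
#' @export
breeding_scheme <- function(n_backcross = 3L, marker_pos_cm = 35,
                            final_cross = TRUE, terminal_sex = "male") {
  if (n_backcross < 0) abort("`n_backcross` must be >= 0")
  structure(list(n_backcross = as.integer(n_backcross),
                 marker_pos_cm = marker_pos_cm,
                 final_cross = isTRUE(final_cross),
                 terminal_sex = match.arg(terminal_sex, c("male", "female"))),
            class = "breeding_scheme")
}

#' Simulate a backcross scheme and measure terminal genome composition
#'
#' Replicates the scheme under the Haldane crossover model and reports, per
#' terminal animal, the length-weighted fractions of the genome (autosomes +
#' X) that are heterozygous, homozygous for the recurrent parent, and
#' donor-derived, plus the heterozygous tract length around the selected
#' marker. Selected females are heterozygous at the marker by construction;
#' if no daughter satisfies the selection within `retry_cap` attempts the
#' replicate errors out.
#'
#' @param scheme A [breeding_scheme()].
#' @param genome A [genome_model()].
#' @param n_replicates Number of independent pedigree replicates.
#' @param seed Integer seed.
#' @param retry_cap Maximum daughters sampled per selection step.
#' @return An object of class `backcross_sim`; `tidy()` gives the
#'   per-replicate tibble, `glance()` the mean/SD/quantile summary of the
#'   homozygous-recurrent fraction.
#' @export
simulate_backcross <- function(scheme, genome = genome_model(),
                               n_replicates = 1000L, seed = 1L,
                               retry_cap = 1000L) {
  stopifnot(inherits(scheme, "breeding_scheme"), inherits(genome, "genome_model"))
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  x_len <- genome$length_cm[genome$chrom == "X"]
  if (!is.null(scheme$marker_pos_cm) &&
      (scheme$marker_pos_cm < 0 || scheme$marker_pos_cm > x_len)) {
    abort("marker position must lie on the X chromosome map")
  }
  with_seed(derive_seed(seed, "backcross"), {
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      donor_f <- founder(genome, 1L, "female")
      recurrent_m <- founder(genome, 2L, "male")
      # F1 female: donor mother x recurrent father
      fem <- cross_individuals(donor_f, recurrent_m, "female", genome)
      if (scheme$n_backcross > 0) {
        for (g in seq_len(scheme$n_backcross)) {
          tries <- 0L
          repeat {
            tries <- tries + 1L
            cand <- cross_individuals(fem, recurrent_m, "female", genome)
            if (is.null(scheme$marker_pos_cm)) break
            gt <- c(hap_at(cand$X[[1]], scheme$marker_pos_cm),
                    hap_at(cand$X[[2]], scheme$marker_pos_cm))
            if (length(unique(gt)) == 2) break
            if (tries >= retry_cap) {
              abort(paste0("selection predicate unsatisfiable in generation ",
                           g, " after ", retry_cap, " attempts"))
            }
          }
          fem <- cand
        }
      }
      terminal <- if (scheme$final_cross) {
        cross_individuals(fem, recurrent_m, scheme$terminal_sex, genome)
      } else fem
      out <- genotype_fractions(terminal, genome)
      out$marker_het_tract_cm <- if (is.null(scheme$marker_pos_cm)) NA_real_
        else het_tract_around(terminal, scheme$marker_pos_cm)
      out$replicate <- r
      out
    })
    structure(list(replicates = dplyr::bind_rows(reps), scheme = scheme,
                   genome = genome, seed = seed),
              class = "backcross_sim")
  })
}

#' @export
print.backcross_sim <- function(x, ...) {
  g <- glance(x)
  cat("<backcross_sim> ", nrow(x$replicates), " replicates\n", sep = "")
  cat(sprintf("  homozygous-recurrent genome fraction: mean %.1f%% (sd %.1f), 5-95%%: %.1f-%.1f\n",
              100 * g$mean_hom_recurrent, 100 * g$sd_hom_recurrent,
              100 * g$q05_hom_recurrent, 100 * g$q95_hom_recurrent))
  invisible(x)
}

#' Tidy and summarise a backcross simulation
#'
#' @param x A `backcross_sim` from [simulate_backcross()].
#' @param ... Unused.
#' @return `tidy()`: one row per replicate with genome fractions; `glance()`:
#'   one row of summary statistics.
#' @method tidy backcross_sim
#' @export
tidy.backcross_sim <- function(x, ...) {
  dplyr::select(x$replicates, "replicate", dplyr::everything())
}

#' @rdname tidy.backcross_sim
#' @method glance backcross_sim
#' @export
glance.backcross_sim <- function(x, ...) {
  r <- x$replicates
  tibble(
    n_replicates = nrow(r),
    mean_hom_recurrent = mean(r$hom_recurrent_frac),
    sd_hom_recurrent = sd(r$hom_recurrent_frac),
    q05_hom_recurrent = quantile(r$hom_recurrent_frac, 0.05, names = FALSE),
    q95_hom_recurrent = quantile(r$hom_recurrent_frac, 0.95, names = FALSE),
    mean_het = mean(r$het_frac),
    mean_het_autosomal = mean(r$het_frac_autosomal),
    mean_donor = mean(r$donor_frac),
    mean_marker_tract_cm = mean(r$marker_het_tract_cm)
  )
}
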