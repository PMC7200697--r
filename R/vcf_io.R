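#' Write per-strain VCF files for a variant panel
#'
#' One VCFv4.2 file per strain: `CHROM, POS` (1-based), `ID` (rsID or "."),
#' `REF, ALT, QUAL`, consequence in `INFO` key `CSQ`, and a single-sample
#' `GT` FORMAT column (`1/1` for homozygous-alt, `0/1` for heterozygous).
#' This is exactly the dialect the variant filter consumes.
#'
#' @param calls Long call tibble with a `strain` column (see
#'   [generate_variant_panel()]).
#' @param dir Output directory, created if needed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_variant_vcf <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (st in sort(unique(calls$strain))) {
    d <- calls[calls$strain == st, ]
    d <- dplyr::arrange(d, .data$chrom, .data$pos)
    gt <- dplyr::case_when(d$genotype == "hom_alt" ~ "1/1",
                           d$genotype == "het" ~ "0/1",
                           d$genotype == "hom_ref" ~ "0/0",
                           TRUE ~ "./.")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", st),
      sprintf("%s\t%d\t%s\t%s\t%s\t%s\t.\tCSQ=%s\tGT\t%s",
              d$chrom, d$pos, ifelse(is.na(d$rsid), ".", d$rsid),
              d$ref, d$alt, format(d$qual, trim = TRUE), d$consequence, gt)
    )
    path <- file.path(dir, paste0(st, ".vcf"))
    writeLines(lines, path)
    paths[st] <- path
  }
  invisible(paths)
}

parse_gt <- function(gt) {
  alleles <- strsplit(sub(":.*", "", gt), "[/|]")
  vapply(alleles, function(a) {
    a <- a[a != "."]
    if (!length(a)) return(NA_character_)
    # hemizygous male X calls ("1") count as homozygous-alt
    if (all(a == "0")) "hom_ref"
    else if (all(a == a[1])) "hom_alt"
    else "het"
  }, character(1))
}

#' Read a single-strain VCF into the call-table dialect
#'
#' Parses with `vcfR`, splits multi-allelic records into per-alt calls, and
#' maps diploid, phased and hemizygous GT encodings onto
#' `hom_ref`/`het`/`hom_alt`. The consequence class is taken from INFO key
#' `CSQ`.
#'
#' @param path VCF file path.
#' @param strain Strain label; defaults to the sample column name.
#' @return Call tibble (`strain`, `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `genotype`, `rsid`, `consequence`).
#' @export
read_variant_vcf <- function(path, strain = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF files requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- if (ncol(v@gt) >= 2) v@gt[, 2] else rep(NA_character_, nrow(fix))
  strain <- strain %||% colnames(v@gt)[2] %||% "unknown"
  csq <- stringr::str_match(fix$INFO %||% "", "CSQ=([^;]+)")[, 2]
  base <- tibble(
    strain = strain,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = as.numeric(fix$QUAL),
    gt_raw = as.character(gt_raw),
    rsid = dplyr::if_else(fix$ID == ".", NA_character_, fix$ID),
    consequence = dplyr::if_else(is.na(csq), "other", csq)
  )
  # split multi-allelic records into one call per alt allele
  base <- tidyr::separate_rows(base, "alt", sep = ",")
  base$genotype <- parse_gt(base$gt_raw)
  dplyr::select(base, -"gt_raw")
}
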