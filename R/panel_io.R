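#' Write a genotype panel as plain TSV files
#'
#' Writes `<prefix>.geno.tsv` (sample_id plus one raw-dosage column per
#' variant) and `<prefix>.vars.tsv` (variant_id, chrom, pos).  Intended for
#' fixtures and small simulated panels, not biobank-scale data.
#'
#' @param panel a [genotype_panel] (raw dosages; standardized panels are
#'   refused since the TSV format is defined on the dosage scale).
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$standardized)
    stop("write_panel expects raw dosages, not a standardized panel")
  geno <- as.data.frame(panel$dosage)
  names(geno) <- panel$variant_id
  geno <- cbind(sample_id = panel$sample_id, geno)
  write.table(geno, paste0(prefix, ".geno.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(variant_id = panel$variant_id, chrom = panel$chrom,
                         pos = panel$pos),
              paste0(prefix, ".vars.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a genotype panel written by [write_panel()]
#' @param prefix path prefix used at write time.
#' @return A [genotype_panel] with raw dosages.
#' @export
read_panel <- function(prefix) {
  gpath <- paste0(prefix, ".geno.tsv"); vpath <- paste0(prefix, ".vars.tsv")
  for (f in c(gpath, vpath)) if (!file.exists(f)) stop("panel file not found: ", f)
  geno <- read.table(gpath, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
  vars <- read.table(vpath, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  X <- as.matrix(geno[, -1L, drop = FALSE])
  if (!identical(colnames(X), as.character(vars$variant_id)))
    stop("variant ids of ", gpath, " and ", vpath, " disagree")
  genotype_panel(X, variant_id = vars$variant_id, chrom = vars$chrom,
                 pos = vars$pos, sample_id = as.character(geno$sample_id))
}

#' Read a PLINK 1 binary fileset (.bed/.bim/.fam)
#'
#' Minimal reader for variant-major PLINK v1.00 .bed files (magic bytes
#' `0x6c 0x1b 0x01`).  Dosages count copies of the A1 allele of the .bim
#' file, which becomes the effect allele of the panel; the two-bit codes
#' 00/10/11 map to dosages 2/1/0 and 01 to missing.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @return A [genotype_panel] with raw dosages and per-variant alleles in
#'   attributes `allele_effect` / `allele_other`.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (f in paths) if (!file.exists(f)) stop("PLINK file not found: ", f)
  bim <- read.table(paths[2L], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "variant_id", "cm", "pos",
                                  "a1", "a2"))
  fam <- read.table(paths[3L], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bed <- readBin(paths[1L], "raw", n = 3L + ceiling(n / 4) * m)
  if (length(bed) < 3L || bed[1L] != as.raw(0x6c) || bed[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1L])
  if (bed[3L] != as.raw(0x01))
    stop("only variant-major (v1.00) .bed files are supported")
  bpv <- ceiling(n / 4)
  body <- bed[-(1:3)]
  if (length(body) < bpv * m) stop("truncated .bed file: ", paths[1L])
  # unpack 2-bit codes, least significant pair first
  codes <- matrix(0L, nrow = 4L * bpv, ncol = m)
  bm <- matrix(as.integer(body[seq_len(bpv * m)]), nrow = bpv)
  for (k in 0:3) codes[seq(k + 1L, 4L * bpv, by = 4L), ] <-
    bm %/% 4L^k %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_real_, n, m)
  dosage[codes == 0L] <- 2; dosage[codes == 2L] <- 1; dosage[codes == 3L] <- 0
  panel <- genotype_panel(dosage, variant_id = bim$variant_id,
                          chrom = as.character(bim$chrom), pos = bim$pos,
                          sample_id = as.character(fam[[2L]]))
  attr(panel, "allele_effect") <- bim$a1
  attr(panel, "allele_other") <- bim$a2
  panel
}
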