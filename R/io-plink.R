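# PLINK 1 binary (bed/bim/fam, SNP-major) reader and writer, and allele
# harmonization across two cohorts. Dosages count copies of the bim A1
# allele; bim positions are kept 1-based as in the format.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 2-bit genotype codes (value -> A1 dosage): 0 -> 2, 1 -> NA (missing),
# 2 -> 1, 3 -> 0
.BED_DECODE <- c(2, NA, 1, 0)

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix path prefix of the `.bed`, `.bim`, `.fam` triple.
#' @return list with `genotypes` (n x p matrix of A1-allele dosages, NA for
#'   missing), `variants` (data.frame: chrom, id, cm, pos, a1, a2), and
#'   `samples` (data.frame: fid, iid, pid, mid, sex, pheno).
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)
  variants <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "id", "cm", "pos",
                                       "a1", "a2"),
                         colClasses = c("character", "character", "numeric",
                                       "integer", "character", "character"))
  samples <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("fid", "iid", "pid", "mid", "sex",
                                      "pheno"))
  n <- nrow(samples)
  p <- nrow(variants)
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = 3L + p * bytesPerSnp)
  if (length(raw) < 3L || !identical(raw[1:3], .BED_MAGIC))
    stop("not a PLINK v1.00 SNP-major bed file (bad magic bytes)")
  body <- raw[-(1:3)]
  if (length(body) != p * bytesPerSnp)
    stop("bed payload size does not match bim/fam dimensions")
  # two bits per sample, little-endian within each byte
  bits <- matrix(as.integer(rawToBits(body)), nrow = 2L)
  codes <- bits[1L, ] + 2L * bits[2L, ]
  codes <- matrix(codes, nrow = 4L * bytesPerSnp)[seq_len(n), , drop = FALSE]
  G <- matrix(.BED_DECODE[codes + 1L], n, p)
  colnames(G) <- variants$id
  list(genotypes = G, variants = variants, samples = samples)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' @param genotypes n x p matrix of A1-allele dosages in \{0, 1, 2, NA\}.
#' @param prefix output path prefix.
#' @param variants optional variant table (chrom, id, cm, pos, a1, a2);
#'   defaults to ids `snp1..p` on chromosome 1 with alleles A/B.
#' @param samples optional sample table (fid, iid, pid, mid, sex, pheno).
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(genotypes, prefix, variants = NULL, samples = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (p < 1L) stop("no variants to write")
  if (!all(genotypes %in% c(0, 1, 2) | is.na(genotypes)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(variants)) {
    variants <- data.frame(chrom = "1", id = paste0("snp", seq_len(p)),
                           cm = 0, pos = seq_len(p), a1 = "A", a2 = "B")
  }
  if (is.null(samples)) {
    samples <- data.frame(fid = paste0("F", seq_len(n)),
                          iid = paste0("I", seq_len(n)),
                          pid = 0L, mid = 0L, sex = 0L, pheno = -9L)
  }
  stopifnot(nrow(variants) == p, nrow(samples) == n)
  # dosage -> 2-bit code (see .BED_DECODE); NA -> 1
  codeOf <- c(3L, 2L, 0L) # dosage 0, 1, 2
  codes <- matrix(1L, n, p)
  ok <- !is.na(genotypes)
  codes[ok] <- codeOf[genotypes[ok] + 1L]
  pad <- (4L - n %% 4L) %% 4L
  if (pad > 0L) codes <- rbind(codes, matrix(0L, pad, p))
  bits <- rbind(as.vector(codes) %% 2L, as.vector(codes) %/% 2L)
  payload <- packBits(as.logical(bits), type = "raw")
  writeBin(c(.BED_MAGIC, payload), paste0(prefix, ".bed"))
  write.table(variants, paste0(prefix, ".bim"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(samples, paste0(prefix, ".fam"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Align two cohorts' variant tables
#'
#' Intersects the two tables on variant id, harmonizes allele orientation —
#' when cohort 2 lists the alleles swapped relative to cohort 1 its dosages
#' must be flipped `x -> 2 - x` — and drops variants whose allele pairs
#' cannot be reconciled, reporting the count.
#'
#' @param variants1,variants2 variant tables as returned by [readPlink()].
#' @return list with `idx1`, `idx2` (row indices into each table, in
#'   matched order), `flip2` (logical: flip cohort 2's dosage at this
#'   variant), and `dropped` (number of shared ids with irreconcilable
#'   alleles).
#' @export
alignCohorts <- function(variants1, variants2) {
  shared <- intersect(variants1$id, variants2$id)
  if (!length(shared)) stop("the cohorts share no variant ids")
  i1 <- match(shared, variants1$id)
  i2 <- match(shared, variants2$id)
  same <- variants1$a1[i1] == variants2$a1[i2] &
    variants1$a2[i1] == variants2$a2[i2]
  swapped <- variants1$a1[i1] == variants2$a2[i2] &
    variants1$a2[i1] == variants2$a1[i2] & !same
  keep <- same | swapped
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " shared variant(s) dropped: irreconcilable alleles")
  if (!any(keep)) stop("no variants left after allele harmonization")
  list(idx1 = i1[keep], idx2 = i2[keep], flip2 = swapped[keep],
       dropped = dropped)
}
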