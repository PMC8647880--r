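#' Construct a genotype matrix
#'
#' Samples x markers alternative-allele dosage in `{0, 1, 2, NA}` plus a
#' marker map (id, chromosome, 1-based position, ref/alt alleles). Positions
#' must be sorted within chromosome.
#'
#' @param samples character sample ids (unique).
#' @param map data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param dosage integer matrix, `length(samples)` x `nrow(map)`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, map, dosage) {
  dosage <- as.matrix(dosage)
  if (anyDuplicated(samples)) stop_config("duplicate sample ids")
  if (anyDuplicated(map$id)) stop_config("duplicate marker id")
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(map))
    stop_config("dosage dimensions do not match samples x markers")
  if (any(map$pos < 0)) stop_config("negative positions")
  ok <- tapply(map$pos, map$chrom, function(p) !is.unsorted(p))
  if (!all(unlist(ok))) stop_config("positions not sorted within chromosome")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop_config("dosage values outside {0,1,2,NA}")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(samples, map$id)
  structure(list(samples = as.character(samples),
                 map = as.data.frame(map, stringsAsFactors = FALSE),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers on %d chromosome(s)\n",
              length(x$samples), nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

call_to_dosage <- function(calls, ref, alt) {
  # calls: character vector of diploid calls for one marker (single-letter
  # IUPAC or two-letter); returns integer dosage of `alt`.
  out <- rep(NA_integer_, length(calls))
  calls <- toupper(calls)
  two <- nchar(calls) == 2L & !calls %in% c("NN", "--")
  one <- nchar(calls) == 1L & !calls %in% "N"
  if (any(one)) {
    c1 <- calls[one]
    expanded <- ifelse(c1 %in% names(iupac_het), iupac_het[c1],
                       paste0(c1, c1))
    calls[one] <- expanded
    two <- two | one
  }
  if (any(two)) {
    a1 <- substr(calls[two], 1, 1)
    a2 <- substr(calls[two], 2, 2)
    d <- (a1 == alt) + (a2 == alt)
    valid <- (a1 == alt | a1 == ref) & (a2 == alt | a2 == ref)
    out[two] <- ifelse(valid, as.integer(d), NA_integer_)
  }
  out
}

#' Read genotypes from a HapMap (.hmp.txt) file
#'
#' Expects the 11 standard metadata columns (`rs#`, `alleles`, `chrom`,
#' `pos`, `strand`, `assembly#`, `center`, `protLSID`, `assayLSID`,
#' `panelLSID`, `QCcode`) followed by one column per sample. Diploid calls
#' may be two-letter (`AA`, `AT`) or single-letter IUPAC (`W` at an A/T site
#' is a heterozygote); `N`, `NN` and `--` become missing. The first allele in
#' the `alleles` field is taken as reference, the second as alternative.
#'
#' @param path file path.
#' @return a `genotype_matrix`.
#' @export
read_hapmap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character", fill = FALSE)
  if (ncol(dt) < 12)
    stop_config("HapMap file needs 11 metadata columns plus >= 1 sample")
  meta <- dt[, 1:11]
  samp_cols <- names(dt)[-(1:11)]
  if (anyDuplicated(meta[[1]]))
    stop_config("duplicated marker id in %s", path)
  alleles <- strsplit(meta[[2]], "/", fixed = TRUE)
  bad_all <- lengths(alleles) != 2
  ref <- vapply(alleles, function(a) toupper(a[1]), "")
  alt <- vapply(alleles, function(a) if (length(a) > 1) toupper(a[2]) else NA_character_, "")
  m <- nrow(meta)
  dos <- matrix(NA_integer_, length(samp_cols), m)
  for (j in seq_len(m)) {
    if (bad_all[j]) next
    dos[, j] <- call_to_dosage(as.character(dt[j, -(1:11)]), ref[j], alt[j])
  }
  map <- data.frame(id = meta[[1]], chrom = meta[[3]],
                    pos = as.integer(meta[[4]]), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  genotype_matrix(samp_cols, map[ord, ], dos[, ord, drop = FALSE])
}

#' Write a genotype matrix as HapMap
#'
#' Two-letter diploid calls; missing dosage becomes `NN`.
#'
#' @param G a `genotype_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hapmap <- function(G, path) {
  map <- G$map
  m <- nrow(map)
  calls <- matrix("NN", m, length(G$samples))
  for (j in seq_len(m)) {
    d <- G$dosage[, j]
    cj <- c(paste0(map$ref[j], map$ref[j]),
            paste0(map$ref[j], map$alt[j]),
            paste0(map$alt[j], map$alt[j]))[d + 1L]
    cj[is.na(d)] <- "NN"
    calls[j, ] <- cj
  }
  out <- data.frame(`rs#` = map$id, alleles = paste0(map$ref, "/", map$alt),
                    chrom = map$chrom, pos = map$pos, strand = "+",
                    `assembly#` = "NA", center = "NA", protLSID = "NA",
                    assayLSID = "NA", panelLSID = "NA", QCcode = "NA",
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(calls, stringsAsFactors = FALSE,
                                  col.names = G$samples))
  names(out)[-(1:11)] <- G$samples
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Summarize a HapMap panel's marker accounting
#'
#' Marker count, per-chromosome counts with max/min, and the mean marker
#' count per chromosome.
#'
#' @param x a `genotype_matrix` or path to a HapMap file.
#' @return list: `n_markers`, `n_samples`, `per_chrom` (named counts),
#'   `max_chrom`, `min_chrom`, `mean_per_chrom`.
#' @export
summarize_hapmap <- function(x) {
  G <- if (inherits(x, "genotype_matrix")) x else read_hapmap(x)
  per <- table(G$map$chrom)
  list(n_markers = nrow(G$map), n_samples = length(G$samples),
       per_chrom = per,
       max_chrom = max(per), min_chrom = min(per),
       mean_per_chrom = mean(per))
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Backed by the VariantAnnotation package. The GT field is mapped to
#' alternative-allele dosage; records with more than one alternative allele
#' are skipped with a warning reporting their count.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_config("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    stop_config("VCF has no GT format field")
  nalt <- lengths(VariantAnnotation::alt(vcf))
  multi <- nalt != 1
  if (any(multi)) {
    warning(sprintf("skipped %d multiallelic record(s)", sum(multi)))
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  tod <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    ifelse(g %in% c("0/0"), 0L,
           ifelse(g %in% c("0/1", "1/0"), 1L,
                  ifelse(g %in% c("1/1"), 2L, NA_integer_)))
  }
  dos <- t(apply(gt, 1, tod))
  if (nrow(gt) == 1L) dos <- matrix(dos, nrow = 1L)
  map <- data.frame(
    id = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(VariantAnnotation::alt(vcf), function(a) as.character(a)[1], ""),
    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  genotype_matrix(colnames(gt), map[ord, ], t(dos)[, ord, drop = FALSE])
}

marker_maf <- function(G) {
  p <- colMeans(G$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter markers by minor allele frequency
#'
#' MAF is computed from non-missing calls; markers with `MAF < min_maf` are
#' removed (a monomorphic marker is removed at any positive threshold).
#'
#' @param G a `genotype_matrix`.
#' @param min_maf threshold in `[0, 0.5]` (default 0.05).
#' @return the filtered `genotype_matrix`, with attribute `"removed"` giving
#'   the removed marker count.
#' @export
filter_maf <- function(G, min_maf = 0.05) {
  if (min_maf < 0 || min_maf > 0.5) stop_config("min_maf must be in [0, 0.5]")
  keep <- marker_maf(G) >= min_maf
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop_config("all markers removed at MAF >= %g", min_maf)
  out <- genotype_matrix(G$samples, G$map[keep, ],
                         G$dosage[, keep, drop = FALSE])
  attr(out, "removed") <- sum(!keep)
  out
}

#' Impute missing dosages
#'
#' In-package replacement for haplotype-model imputation, intended for
#' synthetic or lightly incomplete panels: per marker, missing calls become
#' the modal dosage (`"mode"`) or the rounded mean dosage (`"mean-round"`).
#'
#' @param G a `genotype_matrix`.
#' @param strategy `"mode"` (default) or `"mean-round"`.
#' @param max_missing per-marker missing-fraction cap (default 0.5); markers
#'   above it raise an error listing them.
#' @return the completed `genotype_matrix`, with attribute `"imputed"` (a
#'   logical matrix marking imputed cells) when anything was imputed.
#' @export
impute_missing <- function(G, strategy = c("mode", "mean-round"),
                           max_missing = 0.5) {
  strategy <- match.arg(strategy)
  miss <- is.na(G$dosage)
  if (!any(miss)) return(G)
  frac <- colMeans(miss)
  over <- frac > max_missing
  if (any(over))
    stop_config("marker(s) above missing cap %g: %s", max_missing,
                paste(G$map$id[over], collapse = ", "))
  dos <- G$dosage
  for (j in which(colSums(miss) > 0)) {
    obs <- dos[!miss[, j], j]
    fill <- if (strategy == "mode") {
      as.integer(names(which.max(table(obs))))
    } else {
      as.integer(round(mean(obs)))
    }
    dos[miss[, j], j] <- fill
  }
  out <- genotype_matrix(G$samples, G$map, dos)
  attr(out, "imputed") <- miss
  out
}

#' VanRaden genomic relationship matrix
#'
#' `K = W W' / (2 * sum(p_j (1 - p_j)))` where `W` is the dosage matrix
#' centered per marker at `2 p_j` and `p_j` is the alternative-allele
#' frequency. Symmetric and positive semidefinite by construction.
#'
#' @param G a `genotype_matrix` with no missing calls.
#' @return a `kinship_matrix`: numeric matrix with sample ids as dimnames.
#' @export
kinship_vanraden <- function(G) {
  if (anyNA(G$dosage)) stop_config("kinship requires complete dosages; impute first")
  p <- colMeans(G$dosage) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop_config("need >= 2 polymorphic markers for kinship")
  W <- sweep(G$dosage[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(G$samples, G$samples)
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Principal-component structure covariates
#'
#' First `k` principal-component scores of the marker-centered dosage matrix;
#' the standard substitute for model-based subpopulation membership when no
#' Q matrix is supplied.
#'
#' @param G a `genotype_matrix` with no missing calls.
#' @param k number of components (`k = 0` returns a zero-column matrix).
#' @return numeric matrix (samples x k) with attribute `"source" = "pca"`.
#' @export
structure_pcs <- function(G, k = 3L) {
  if (k >= length(G$samples)) stop_config("k must be < number of samples")
  if (k == 0L) {
    out <- matrix(numeric(0), length(G$samples), 0,
                  dimnames = list(G$samples, NULL))
    attr(out, "source") <- "pca"
    return(out)
  }
  if (anyNA(G$dosage)) stop_config("structure PCs require complete dosages")
  X <- scale(G$dosage, center = TRUE, scale = FALSE)
  pc <- prcomp(X, center = FALSE)
  out <- pc$x[, seq_len(k), drop = FALSE]
  rownames(out) <- G$samples
  attr(out, "source") <- "pca"
  out
}

#' Read a Q (population-structure membership) matrix
#'
#' Tab-delimited: first column sample id, remaining columns membership
#' proportions or scores. Takes precedence over PCA covariates in the
#' pipeline when supplied.
#'
#' @param path file path.
#' @return numeric matrix with sample-id rownames and attribute
#'   `"source" = "file"`.
#' @export
read_q_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  out <- as.matrix(dt[-1])
  rownames(out) <- dt[[1]]
  attr(out, "source") <- "file"
  out
}
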