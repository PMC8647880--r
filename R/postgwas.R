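#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`: with sorted p-values `p_(1) <= ... <=
#' p_(m)`, find the largest `k` with `p_(k) <= k q / m`; all p-values up to
#' `p_(k)` are flagged. Adjusted q-values are the usual step-up minima.
#' NA p-values get NA flags and do not count toward `m`.
#'
#' @param pvalues numeric vector in `(0, 1]` (NAs allowed).
#' @param q FDR level.
#' @return list: `significant` (logical, input order), `q` (adjusted
#'   q-values), `p_cutoff` (largest flagged p, or NA when none).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) stop_config("empty p-value vector")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1))
    stop_config("p-values must lie in (0, 1]")
  m <- sum(ok)
  qv <- rep(NA_real_, length(pvalues))
  sig <- rep(NA, length(pvalues))
  if (m > 0) {
    p <- pvalues[ok]
    o <- order(p)
    ranked <- p[o] * m / seq_len(m)
    qs <- rev(cummin(rev(pmin(ranked, 1))))
    qv_ok <- numeric(m)
    qv_ok[o] <- qs
    qv[ok] <- qv_ok
    k <- which(p[o] <= seq_len(m) / m * q)
    cutoff <- if (length(k)) p[o][max(k)] else NA_real_
    sig[ok] <- if (is.na(cutoff)) FALSE else p <= cutoff
  } else {
    cutoff <- NA_real_
  }
  list(significant = sig, q = qv, p_cutoff = cutoff)
}

#' Flanking region around a peak marker
#'
#' `[max(1, pos - window), pos + window]`, 1-based inclusive, clipped to the
#' chromosome length when known. The default 150-kb window suits panels
#' whose LD decays over roughly that scale.
#'
#' @param chrom chromosome name.
#' @param pos peak position (1-based bp).
#' @param window_bp flank half-width (default 150000).
#' @param chrom_lengths optional named vector of chromosome lengths; an
#'   unknown chromosome then raises an error.
#' @param peak_id optional marker id carried through.
#' @return one-row data.frame: chrom, start, end, peak_pos, peak_id.
#' @export
flanking_region <- function(chrom, pos, window_bp = 150000,
                            chrom_lengths = NULL, peak_id = NA_character_) {
  if (window_bp < 0) stop_config("window must be >= 0")
  end <- pos + window_bp
  if (!is.null(chrom_lengths)) {
    if (!chrom %in% names(chrom_lengths))
      stop_config("unknown chromosome '%s' in chrom_lengths", chrom)
    end <- min(end, chrom_lengths[[chrom]])
  }
  data.frame(chrom = chrom, start = max(1, pos - window_bp), end = end,
             peak_pos = pos, peak_id = peak_id, stringsAsFactors = FALSE)
}

#' QTL regions from significant GWAS markers
#'
#' Takes the significant markers of a `gwas_result`, draws the flanking
#' window around each, and merges overlapping windows on the same
#' chromosome into one region; the region's peak is its strongest marker
#' (smallest p, or largest importance for the SVR engine).
#'
#' @param res a `gwas_result`.
#' @param window_bp flank half-width.
#' @param chrom_lengths optional named chromosome lengths for clipping.
#' @return data.frame of regions (chrom, start, end, peak_id, peak_pos,
#'   n_markers, engine); zero rows when nothing is significant.
#' @export
extract_regions <- function(res, window_bp = 150000, chrom_lengths = NULL) {
  sig <- res[!is.na(res$significant) & res$significant, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_id = character(),
                      peak_pos = numeric(), n_markers = integer(),
                      engine = character(), stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  strength <- if (!is.null(sig$p)) -log10(sig$p) else sig$importance
  out <- lapply(split(seq_len(nrow(sig)), sig$chrom), function(ii) {
    s <- sig[ii, ]
    st <- pmax(1, s$pos - window_bp)
    en <- s$pos + window_bp
    if (!is.null(chrom_lengths) && s$chrom[1] %in% names(chrom_lengths))
      en <- pmin(en, chrom_lengths[[s$chrom[1]]])
    ir <- IRanges::IRanges(start = st, end = en)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    do.call(rbind, lapply(seq_along(red), function(k) {
      mk <- which(grp == k)
      peak <- mk[which.max(strength[ii][mk])]
      data.frame(chrom = s$chrom[1],
                 start = IRanges::start(red)[k], end = IRanges::end(red)[k],
                 peak_id = s$marker[peak], peak_pos = s$pos[peak],
                 n_markers = length(mk), engine = s$engine[1],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Linkage-disequilibrium decay
#'
#' Pairwise `r^2` between markers on the same chromosome within
#' `max_dist_bp`, averaged in distance bins of width `bin_bp`. The decay
#' summary is the distance at which a running-mean smooth of the binned
#' curve first falls below half its maximum (NA when never reached).
#' Monomorphic markers are excluded with a warning.
#'
#' @param G a `genotype_matrix` with complete dosages and positions.
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp distance bin width.
#' @return list: `bins` (data.frame dist_mid, mean_r2, n_pairs),
#'   `half_decay_bp` (possibly NA), `max_r2`.
#' @export
ld_decay <- function(G, max_dist_bp = 1e6, bin_bp = 1e4) {
  if (anyNA(G$dosage)) stop_config("impute before LD computation")
  mono <- apply(G$dosage, 2, function(g) all(g == g[1]))
  if (any(mono))
    warning(sprintf("%d monomorphic marker(s) excluded from LD", sum(mono)))
  keep <- !mono
  if (sum(keep) < 2) stop_config("fewer than 2 polymorphic markers")
  map <- G$map[keep, , drop = FALSE]
  dos <- G$dosage[, keep, drop = FALSE]
  dists <- numeric(0); r2 <- numeric(0)
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    if (length(jj) < 2) next
    pos <- map$pos[jj]
    Z <- scale(dos[, jj, drop = FALSE])
    for (a in seq_len(length(jj) - 1)) {
      bmax <- a
      while (bmax < length(jj) && pos[bmax + 1] - pos[a] <= max_dist_bp)
        bmax <- bmax + 1
      if (bmax == a) next
      bs <- (a + 1):bmax
      rr <- as.vector(crossprod(Z[, a], Z[, bs, drop = FALSE])) /
        (nrow(Z) - 1)
      dists <- c(dists, pos[bs] - pos[a])
      r2 <- c(r2, rr^2)
    }
  }
  if (length(r2) == 0) stop_config("no marker pairs within max_dist_bp")
  bin <- pmin(dists %/% bin_bp, ceiling(max_dist_bp / bin_bp) - 1)
  agg <- tapply(r2, bin, mean)
  cnt <- tapply(r2, bin, length)
  mids <- (as.numeric(names(agg)) + 0.5) * bin_bp
  o <- order(mids)
  bins <- data.frame(dist_mid = mids[o], mean_r2 = as.numeric(agg)[o],
                     n_pairs = as.integer(cnt)[o])
  sm <- if (nrow(bins) >= 5) {
    stats::filter(bins$mean_r2, rep(1 / 3, 3), sides = 2)
  } else bins$mean_r2
  sm[is.na(sm)] <- bins$mean_r2[is.na(sm)]
  half <- max(sm) / 2
  below <- which(sm <= half)
  half_decay <- if (length(below)) bins$dist_mid[below[1]] else NA_real_
  list(bins = bins, half_decay_bp = half_decay, max_r2 = max(sm))
}

#' Allelic effect of a marker on a trait
#'
#' Mean trait value of reference homozygotes (dosage 0) and alternative
#' homozygotes (dosage 2), their difference (alt - ref), heterozygote mean,
#' and class counts. An empty homozygote class is reported as missing with
#' a warning.
#'
#' @param y genotype-level trait values (named or aligned to `G$samples`).
#' @param G a `genotype_matrix`.
#' @param marker marker id or column index.
#' @return list: `ref_mean`, `het_mean`, `alt_mean`, `difference`,
#'   `n` (counts per class).
#' @export
allelic_effect <- function(y, G, marker) {
  y <- align_phenotype(y, G)
  j <- if (is.character(marker)) match(marker, G$map$id) else as.integer(marker)
  if (is.na(j) || j < 1 || j > ncol(G$dosage))
    stop_config("marker '%s' not found", as.character(marker))
  d <- G$dosage[, j]
  mn <- function(cls) {
    v <- y[d == cls]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- list(ref_mean = mn(0L), het_mean = mn(1L), alt_mean = mn(2L),
              difference = NA_real_,
              n = c(ref = sum(d == 0, na.rm = TRUE),
                    het = sum(d == 1, na.rm = TRUE),
                    alt = sum(d == 2, na.rm = TRUE)))
  if (is.na(out$ref_mean) || is.na(out$alt_mean))
    warning("empty homozygote class; reported as missing")
  else out$difference <- out$alt_mean - out$ref_mean
  out
}

#' Read gene models from a GFF3 file
#'
#' Imports via rtracklayer and keeps `gene` features only.
#'
#' @param path GFF3 path.
#' @param feature_type feature to retain (default `"gene"`).
#' @return data.frame: gene_id, chrom, start, end, strand, attributes.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else
    if ("Name" %in% names(md)) as.character(md$Name) else
      paste0("gene", seq_along(gr))
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             attributes = if ("Note" %in% names(md))
               vapply(md$Note, function(x) paste(x, collapse = ";"), "")
             else "",
             stringsAsFactors = FALSE)
}

#' Genes overlapping QTL regions
#'
#' Any-overlap convention on 1-based inclusive coordinates: a gene is
#' reported under a region when they share at least one base, with the
#' overlap length.
#'
#' @param regions data.frame with chrom, start, end (e.g. from
#'   [extract_regions()]).
#' @param genes data.frame with gene_id, chrom, start, end (e.g. from
#'   [read_gff3()]).
#' @return data.frame: region chrom/start/end (+ peak_id when present),
#'   gene_id, gene_start, gene_end, overlap_bp.
#' @export
overlap_genes <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0)
    return(data.frame())
  if (!any(genes$chrom %in% regions$chrom))
    stop_config(paste("no shared chromosome names between regions (%s) and",
                      "genes (%s); rename one side"),
                paste(unique(regions$chrom), collapse = ","),
                paste(unique(genes$chrom), collapse = ","))
  out <- list()
  for (chr in intersect(unique(regions$chrom), unique(genes$chrom))) {
    rr <- regions[regions$chrom == chr, , drop = FALSE]
    gg <- genes[genes$chrom == chr, , drop = FALSE]
    ir_r <- IRanges::IRanges(rr$start, rr$end)
    ir_g <- IRanges::IRanges(gg$start, gg$end)
    hits <- IRanges::findOverlaps(ir_r, ir_g)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(rr$end[qi], gg$end[si]) - pmax(rr$start[qi], gg$start[si]) + 1
    res <- data.frame(chrom = chr, region_start = rr$start[qi],
                      region_end = rr$end[qi],
                      gene_id = gg$gene_id[si], gene_start = gg$start[si],
                      gene_end = gg$end[si], overlap_bp = ov,
                      stringsAsFactors = FALSE)
    if ("peak_id" %in% names(rr)) res$peak_id <- rr$peak_id[qi]
    out[[chr]] <- res
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export regions as BED
#'
#' Converts 1-based inclusive regions to BED's 0-based half-open intervals.
#'
#' @param regions data.frame with chrom, start, end (1-based inclusive).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1,
                    end = regions$end,
                    name = regions$peak_id %||% ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
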