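# LD between causal loci and their flanking markers, summarised by MAF
# category. r2 is the squared Pearson correlation of allele dosages
# (composite LD): phase is not represented in the data model, and two loci
# with very different allele frequencies cannot reach high dosage r2 no
# matter how strong their haplotype association.

#' Squared dosage correlation between two loci
#'
#' @param x1,x2 Dosage vectors of equal length; animals missing either call
#'   are dropped. Both must be polymorphic on the retained animals.
#' @return r2 in `[0, 1]`.
#' @export
dosage_r2 <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("columns differ in length", call. = FALSE)
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    stop("r2 undefined for a constant dosage column", call. = FALSE)
  }
  stats::cor(x1, x2)^2
}

#' LD between QTLs and their flanking markers
#'
#' For each QTL, finds the nearest marker on each side within the same
#' chromosome, computes both dosage r2 values and records their maximum.
#' QTLs at a chromosome edge keep the single available flank and are flagged.
#'
#' @param panel A `genotype_panel`.
#' @param qtls A `qtl_set`.
#' @param marker_panel Marker set name for [marker_ids()] (default
#'   `"sparse50"`); QTL columns themselves are excluded from the markers.
#' @return Object of class `ld_profile`: data.frame with `qtl_id`, `chrom`,
#'   `pos`, `maf`, `left_r2`, `right_r2`, `max_r2`, `edge`; the QTL category
#'   is kept as an attribute.
#' @export
qtl_flanking_r2 <- function(panel, qtls, marker_panel = "sparse50") {
  mids <- setdiff(marker_ids(panel, marker_panel), qtls$snp_id)
  if (length(mids) == 0) stop("no markers available", call. = FALSE)
  map_ids <- as.character(panel$map$snp_id)
  midx <- match(mids, map_ids)
  p <- allele_frequencies(panel)
  rows <- lapply(seq_along(qtls$snp_id), function(k) {
    qi <- qtls$index[k]
    qch <- panel$map$chrom[qi]
    qpos <- panel$map$pos[qi]
    same <- midx[panel$map$chrom[midx] == qch]
    lpos <- same[panel$map$pos[same] < qpos]
    rpos <- same[panel$map$pos[same] > qpos]
    left_i <- if (length(lpos)) lpos[which.max(panel$map$pos[lpos])] else NA_integer_
    right_i <- if (length(rpos)) rpos[which.min(panel$map$pos[rpos])] else NA_integer_
    r2_of <- function(i) {
      if (is.na(i)) return(NA_real_)
      tryCatch(dosage_r2(panel$dosages[, qi], panel$dosages[, i]),
               error = function(e) NA_real_)
    }
    lr2 <- r2_of(left_i); rr2 <- r2_of(right_i)
    if (is.na(lr2) && is.na(rr2)) return(NULL)
    data.frame(qtl_id = qtls$snp_id[k], chrom = qch, pos = qpos,
               maf = min(p[qi], 1 - p[qi]),
               left_r2 = lr2, right_r2 = rr2,
               max_r2 = max(lr2, rr2, na.rm = TRUE),
               edge = is.na(left_i) || is.na(right_i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(out, category = qtls$category,
            class = c("ld_profile", "data.frame"))
}

#' Summarise an LD profile
#'
#' Histogram proportions of the per-QTL maximum flanking r2 over equal-width
#' bins on `[0, 1]`, plus the profile mean.
#'
#' @param profile An `ld_profile`.
#' @param bins Number of bins.
#' @return List with `density` (data.frame: `bin_lo`, `bin_hi`, `proportion`)
#'   and `mean_r2`.
#' @export
summarize_r2 <- function(profile, bins = 20L) {
  if (nrow(profile) == 0) stop("empty LD profile", call. = FALSE)
  breaks <- seq(0, 1, length.out = bins + 1L)
  cnt <- table(cut(profile$max_r2, breaks, include.lowest = TRUE))
  list(
    density = data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                         proportion = as.numeric(cnt) / nrow(profile)),
    mean_r2 = mean(profile$max_r2)
  )
}
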