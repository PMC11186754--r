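SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G",
                          "complex", "MNV")

#' Classify a ref/alt pair into a substitution class
#'
#' Single-base substitutions are collapsed to the pyrimidine-reference
#' convention (a purine reference is reverse-complemented together with its
#' alternate), giving the six classes C>A, C>G, C>T, T>A, T>C, T>G.
#' Equal-length multi-base substitutions are MNV; every other shape
#' (insertions, deletions, mixed-length replacements) is complex.
#'
#' @param ref,alt allele strings (vectorized, equal length); `ref != alt`,
#'   non-empty.
#' @return character vector of class labels.
#' @export
classify_substitution <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("empty allele string")
  if (any(ref == alt)) stop("ref and alt must differ")
  ref <- toupper(ref); alt <- toupper(alt)
  out <- character(length(ref))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L
  if (any(snv)) {
    r <- ref[snv]; a <- alt[snv]
    flip <- r %in% c("A", "G")
    r[flip] <- chartr("ACGT", "TGCA", r[flip])
    a[flip] <- chartr("ACGT", "TGCA", a[flip])
    out[snv] <- paste0(r, ">", a)
  }
  mnv <- !snv & nchar(ref) == nchar(alt)
  out[mnv] <- "MNV"
  out[!snv & !mnv] <- "complex"
  out
}

#' Cumulative mutations-per-megabase curve by substitution class
#'
#' For each minimal-VAF threshold on the grid, counts the somatic variants
#' of each substitution class whose VAF in the chosen sample is at least
#' the threshold, and divides by the targeted footprint in megabases.
#'
#' @param variants canonical variant table ([variant_table()]).
#' @param sample `"biopsy"` or `"resection"`.
#' @param vaf_grid ascending thresholds in `[0, 1]`.
#' @param region_mb targeted footprint in megabases (default 1.94, a
#'   typical coding footprint of a 500-gene panel).
#' @param posterior_min somatic-posterior threshold for inclusion.
#' @return data frame of class `spectrum_curve` with columns `sample`,
#'   `class`, `vaf_threshold`, `count`, `per_mb`, and attributes
#'   `region_mb`, `sample`.
#' @export
spectrum_curve <- function(variants, sample = c("biopsy", "resection"),
                           vaf_grid = seq(0, 0.5, by = 0.05),
                           region_mb = 1.94, posterior_min = 0.95) {
  sample <- match.arg(sample)
  stopifnot(region_mb > 0)
  if (!length(vaf_grid)) stop("empty VAF grid")
  if (is.unsorted(vaf_grid, strictly = TRUE))
    stop("VAF grid must be strictly ascending")
  variants <- variant_table(variants)
  variants <- variants[variants$somatic_posterior >= posterior_min, ,
                       drop = FALSE]
  vaf <- variants[[paste0("vaf_", sample)]]
  keep <- !is.na(vaf)
  vaf <- vaf[keep]
  cls <- if (any(keep))
    classify_substitution(variants$ref[keep], variants$alt[keep])
  else character(0)
  grid <- expand.grid(class = SUBSTITUTION_CLASSES,
                      vaf_threshold = vaf_grid,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(cl, t) sum(cls == cl & vaf >= t),
                       grid$class, grid$vaf_threshold)
  grid$per_mb <- grid$count / region_mb
  out <- data.frame(sample = sample, grid, stringsAsFactors = FALSE)
  out <- out[order(match(out$class, SUBSTITUTION_CLASSES),
                   out$vaf_threshold), ]
  rownames(out) <- NULL
  attr(out, "region_mb") <- region_mb
  attr(out, "sample") <- sample
  class(out) <- c("spectrum_curve", "data.frame")
  out
}
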