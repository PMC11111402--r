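#' Classify a single-base substitution into its SBS-96 channel
#'
#' Substitutions with a purine reference base (A or G) are
#' reverse-complemented — including both flanking bases — so that every
#' channel is expressed relative to the pyrimidine of the mutated base pair.
#'
#' @param ref,alt reference and alternate bases (single characters,
#'   vectorized).
#' @param context5,context3 immediate 5' and 3' flanking bases (at least one
#'   base each; only the adjacent base is used).
#' @return character vector of SBS-96 labels such as \code{"A[C>A]A"};
#'   \code{NA} for records whose context contains N (unclassifiable).
#' @export
classify_sbs <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("classify_sbs: ref and alt must be single bases (not an SNV)")
  if (any(ref == alt))
    stop("classify_sbs: ref and alt must differ")
  if (any(nchar(context5) < 1L | nchar(context3) < 1L))
    stop("classify_sbs: at least one base of 5' and 3' context required")
  f5 <- substr(context5, nchar(context5), nchar(context5))
  f3 <- substr(context3, 1L, 1L)
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("classify_sbs: ref/alt must be over A,C,G,T")
  unclass <- !(f5 %in% c("A", "C", "G", "T")) | !(f3 %in% c("A", "C", "G", "T"))
  # purine-centred records flip to the opposite strand
  flip <- ref %in% c("A", "G")
  cmp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  r <- ifelse(flip, cmp[ref], ref)
  a <- ifelse(flip, cmp[alt], alt)
  p5 <- ifelse(flip, cmp[f3], f5)
  p3 <- ifelse(flip, cmp[f5], f3)
  out <- paste0(p5, "[", r, ">", a, "]", p3)
  out[unclass] <- NA_character_
  unname(out)
}

#' Classify a substitution into its SBS-288 channel
#'
#' SBS-288 extends SBS-96 with the transcriptional strand of the pyrimidine
#' base: \code{T:} transcribed, \code{U:} untranscribed, \code{N:} unknown
#' (intergenic or unannotated). Collapsing over the strand component
#' reproduces [classify_sbs()] exactly.
#'
#' @inheritParams classify_sbs
#' @param strand one of \code{"transcribed"}, \code{"untranscribed"},
#'   \code{"unknown"} (vectorized).
#' @return SBS-288 labels such as \code{"T:A[C>A]A"}.
#' @export
classify_sbs288 <- function(ref, alt, context5, context3, strand) {
  base <- classify_sbs(ref, alt, context5, context3)
  code <- c(transcribed = "T", untranscribed = "U", unknown = "N")[strand]
  if (any(is.na(code) & !is.na(strand)))
    stop("classify_sbs288: strand must be transcribed/untranscribed/unknown")
  out <- paste0(code, ":", base)
  out[is.na(base)] <- NA_character_
  unname(out)
}

#' Collapse an SBS-288 label to its SBS-96 label
#' @param label SBS-288 channel labels.
#' @return SBS-96 labels.
#' @export
collapse_sbs288 <- function(label) {
  substr(label, 3L, nchar(label))
}

#' Classify a doublet-base substitution into its DBS-78 channel
#'
#' Doublets not in canonical orientation are reverse-complemented; for
#' palindromic reference doublets the orientation of the alternate allele is
#' fixed by the canonical channel table.
#'
#' @param ref,alt reference and alternate dinucleotides differing at both
#'   positions (vectorized).
#' @return DBS-78 labels such as \code{"CT>AA"}; \code{NA} when ref or alt
#'   contains N.
#' @export
classify_dbs <- function(ref, alt) {
  n <- length(ref)
  stopifnot(length(alt) == n)
  if (any(nchar(ref) != 2L | nchar(alt) != 2L))
    stop("classify_dbs: ref and alt must be dinucleotides")
  d1 <- substr(ref, 1, 1) != substr(alt, 1, 1)
  d2 <- substr(ref, 2, 2) != substr(alt, 2, 2)
  if (any(!(d1 & d2)))
    stop("classify_dbs: not a DBS (positions must differ at both bases)")
  hasN <- grepl("N", ref) | grepl("N", alt)
  canon <- dbs78_channels()
  fwd <- paste0(ref, ">", alt)
  rev <- paste0(revcomp(ref), ">", revcomp(alt))
  out <- ifelse(fwd %in% canon, fwd,
                ifelse(rev %in% canon, rev, NA_character_))
  if (any(is.na(out) & !hasN))
    stop("classify_dbs: internal error - doublet not covered by channel table")
  out[hasN] <- NA_character_
  out
}

# longest number of whole copies of `unit` at the start of `s`
.prefix_copies <- function(s, unit) {
  k <- nchar(unit)
  n <- 0L
  while (substr(s, n * k + 1L, (n + 1L) * k) == unit) n <- n + 1L
  n
}

# longest number of whole copies of `unit` at the end of `s`
.suffix_copies <- function(s, unit) {
  k <- nchar(unit)
  L <- nchar(s)
  n <- 0L
  while (n * k + k <= L &&
         substr(s, L - (n + 1L) * k + 1L, L - n * k) == unit) n <- n + 1L
  n
}

# longest common prefix length of two strings
.lcp <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < m && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L))
    i <- i + 1L
  i
}

#' Classify an insertion or deletion into its ID-83 channel
#'
#' Input is VCF-style and left-aligned: \code{ref} and \code{alt} share an
#' anchor prefix which is stripped before classification (the stripped bases
#' are re-appended to the 5' context). Binning conventions:
#' \itemize{
#'   \item 1-bp indels are assigned to a C or T channel after pyrimidine
#'     canonicalization of the indel base, with the repeat field counting,
#'     for deletions, the homopolymer copies of the base including the
#'     deleted one minus 1 (capped at 5, i.e. 6+ copies), and for
#'     insertions the copies already present (capped at 5).
#'   \item longer indels use the repeat-unit count with the same caps; the
#'     displayed length is capped at 5 (5+).
#'   \item deletions of length >= 2 with no whole-unit repeat but partial
#'     homology between the deleted sequence and its flanks fall in the
#'     microhomology channels; homology is the longer of the 5'-suffix and
#'     3'-prefix matches, capped at \code{min(length - 1, 5)}.
#' }
#'
#' @param ref,alt VCF REF and ALT strings (one a prefix of the other after
#'   left alignment; vectorized).
#' @param context5,context3 flanking reference sequence, at least 10 nt each
#'   side (after anchor re-attachment).
#' @return ID-83 labels such as \code{"1:Del:T:4"} or \code{"3:Del:M:2"}.
#' @export
classify_indel <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  vapply(seq_len(n), function(i) {
    .classify_indel_one(ref[i], alt[i], context5[i], context3[i])
  }, character(1))
}

.classify_indel_one <- function(ref, alt, c5, c3) {
  if (nchar(ref) == 0L || nchar(alt) == 0L)
    stop("classify_indel: ref and alt must be non-empty (VCF anchor style)")
  # strip shared prefix into the 5' context
  p <- .lcp(ref, alt)
  if (p > 0L) {
    c5 <- paste0(c5, substr(ref, 1L, p))
    ref <- substr(ref, p + 1L, nchar(ref))
    alt <- substr(alt, p + 1L, nchar(alt))
  }
  # strip shared suffix into the 3' context
  s <- .lcp(paste(rev(strsplit(ref, "")[[1]]), collapse = ""),
            paste(rev(strsplit(alt, "")[[1]]), collapse = ""))
  if (s > 0L) {
    c3 <- paste0(substr(ref, nchar(ref) - s + 1L, nchar(ref)), c3)
    ref <- substr(ref, 1L, nchar(ref) - s)
    alt <- substr(alt, 1L, nchar(alt) - s)
  }
  if (nchar(ref) > 0L && nchar(alt) > 0L)
    stop("classify_indel: complex indel (substitution + indel) is unclassifiable")
  if (nchar(ref) == 0L && nchar(alt) == 0L)
    stop("classify_indel: ref equals alt")
  is_del <- nchar(ref) > 0L
  seqv <- if (is_del) ref else alt
  L <- nchar(seqv)
  if (nchar(c5) < 10L || nchar(c3) < 10L)
    stop("classify_indel: at least 10 nt of flanking context required")
  if (grepl("N", seqv)) return(NA_character_)
  copies3 <- .prefix_copies(c3, seqv)
  copies5 <- .suffix_copies(c5, seqv)
  adj <- copies3 + copies5
  if (L == 1L) {
    base <- if (seqv %in% c("C", "T")) seqv else chartr("AG", "TC", seqv)
    if (is_del) {
      ncopies <- 1L + adj
      return(paste0("1:Del:", base, ":", min(ncopies, 6L) - 1L))
    }
    return(paste0("1:Ins:", base, ":", min(adj, 5L)))
  }
  Lc <- min(L, 5L)
  if (!is_del) return(paste0(Lc, ":Ins:R:", min(adj, 5L)))
  if (adj >= 1L) {
    ncopies <- 1L + adj
    return(paste0(Lc, ":Del:R:", min(ncopies, 6L) - 1L))
  }
  # no whole-unit repeat: look for partial homology with the flanks
  h3 <- .lcp(seqv, c3)
  rs <- paste(rev(strsplit(seqv, "")[[1]]), collapse = "")
  rc5 <- paste(rev(strsplit(c5, "")[[1]]), collapse = "")
  h5 <- .lcp(rs, rc5)
  h <- min(max(h3, h5), L - 1L, 5L)
  if (h >= 1L) return(paste0(Lc, ":Del:M:", h))
  paste0(Lc, ":Del:R:0")
}
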