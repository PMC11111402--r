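#' Channel schemas for mutational catalogues
#'
#' A channel schema is a fixed, ordered partition of somatic mutations into
#' classes. Four schemas are supported:
#' \describe{
#'   \item{SBS96}{single-base substitutions in pyrimidine-centric
#'     trinucleotide context, \code{"A[C>A]A"} ... \code{"T[T>G]T"};
#'     ordered class-major (C>A, C>G, C>T, T>A, T>C, T>G) then by
#'     5' and 3' flank (A, C, G, T).}
#'   \item{SBS288}{SBS96 crossed with transcriptional strand
#'     (\code{T:} transcribed, \code{U:} untranscribed, \code{N:} unknown),
#'     strand-major order.}
#'   \item{DBS78}{canonical doublet-base substitutions, \code{"AC>CA"} ...}
#'   \item{ID83}{small insertions/deletions by type, length, repeat context
#'     and microhomology, \code{"1:Del:C:0"} ... \code{"5:Del:M:5"}.}
#' }
#'
#' @param name one of \code{"SBS96"}, \code{"SBS288"}, \code{"DBS78"},
#'   \code{"ID83"}.
#' @return an object of class \code{channel_schema}: a list with elements
#'   \code{name} and \code{channels} (ordered character vector of unique
#'   labels).
#' @export
channel_schema <- function(name = c("SBS96", "SBS288", "DBS78", "ID83")) {
  name <- match.arg(name)
  channels <- switch(name,
    SBS96  = sbs96_channels(),
    SBS288 = sbs288_channels(),
    DBS78  = dbs78_channels(),
    ID83   = id83_channels()
  )
  structure(list(name = name, channels = channels), class = "channel_schema")
}

#' @export
print.channel_schema <- function(x, ...) {
  cat("<channel_schema>", x$name, "with", length(x$channels), "channels\n")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

sbs96_channels <- function() {
  out <- character(0)
  for (cls in SBS_CLASSES) {
    ref <- substr(cls, 1, 1)
    alt <- substr(cls, 3, 3)
    for (f5 in BASES) for (f3 in BASES) {
      out <- c(out, paste0(f5, "[", ref, ">", alt, "]", f3))
    }
  }
  out
}

sbs288_channels <- function() {
  as.vector(vapply(c("T", "U", "N"),
                   function(s) paste0(s, ":", sbs96_channels()),
                   character(96)))
}

# Canonical DBS-78 labels: 10 canonical reference doublets, palindromic
# references (AT, CG, GC, TA) keep only one of each reverse-complement alt
# pair.
dbs78_channels <- function() {
  tab <- list(
    AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
    AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
    CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
    CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
    CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
    GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
    TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
    TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
    TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
    TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG")
  )
  unlist(lapply(names(tab), function(r) paste0(r, ">", tab[[r]])),
         use.names = FALSE)
}

# ID-83 machine labels. For deletions the final field is the number of
# copies of the deleted unit in the reference (including the deleted copy)
# minus one, capped at 5; for insertions the number of copies already
# present, capped at 5. Microhomology channels (":M:") exist only for
# deletions of length >= 2 with partial-unit homology and no full-unit
# repeat.
id83_channels <- function() {
  ch <- character(0)
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Ins:", b, ":", 0:5))
  for (L in 2:5) ch <- c(ch, paste0(L, ":Del:R:", 0:5))
  for (L in 2:5) ch <- c(ch, paste0(L, ":Ins:R:", 0:5))
  # length-5 deletion channels stand for 5+, whose homology can reach 5
  ch <- c(ch,
          paste0("2:Del:M:", 1),
          paste0("3:Del:M:", 1:2),
          paste0("4:Del:M:", 1:3),
          paste0("5:Del:M:", 1:5))
  ch
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over A, C, G, T (and N).
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}
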