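#' Determine the mutation type of VCF-style records
#'
#' @param ref,alt REF/ALT strings.
#' @return factor with levels \code{SNV}, \code{DBS}, \code{indel},
#'   \code{other}.
#' @export
mutation_type <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  type <- rep("other", length(ref))
  type[nr == 1L & na == 1L & ref != alt] <- "SNV"
  isd <- nr == 2L & na == 2L &
    substr(ref, 1, 1) != substr(alt, 1, 1) &
    substr(ref, 2, 2) != substr(alt, 2, 2)
  type[isd] <- "DBS"
  type[nr != na & (startsWith(ref, alt) | startsWith(alt, ref))] <- "indel"
  factor(type, levels = c("SNV", "DBS", "indel", "other"))
}

#' Build a per-sample mutational catalogue
#'
#' Classifies every mutation record matching the schema's mutation type and
#' tabulates counts per channel and sample. Records of a different type are
#' skipped; records the classifier cannot place (e.g. N in context) are
#' logged as unclassifiable. Input order does not affect the result.
#'
#' @param muts data frame with columns \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{context5}, \code{context3}
#'   and optionally \code{strand} (for SBS288).
#' @param schema a [channel_schema()] or schema name.
#' @param sample_ids optional character vector fixing sample order; samples
#'   seen in \code{muts} but not listed are appended.
#' @return object of class \code{catalogue_matrix}: list with \code{schema},
#'   \code{sample_ids}, \code{counts} (channels x samples integer matrix)
#'   and \code{log} (classification accounting).
#' @export
build_catalogue <- function(muts, schema, sample_ids = NULL) {
  if (is.character(schema)) schema <- channel_schema(schema)
  stopifnot(inherits(schema, "channel_schema"))
  req <- c("sample_id", "ref", "alt", "context5", "context3")
  if (!all(req %in% names(muts)))
    stop("build_catalogue: muts must have columns ",
         paste(req, collapse = ", "))
  want_type <- switch(schema$name,
                      SBS96 = "SNV", SBS288 = "SNV",
                      DBS78 = "DBS", ID83 = "indel")
  type <- mutation_type(muts$ref, muts$alt)
  keep <- !is.na(type) & type == want_type
  n_skipped_type <- sum(!keep)
  m <- muts[keep, , drop = FALSE]
  labels <- if (nrow(m) == 0L) {
    character(0)
  } else {
    switch(schema$name,
      SBS96  = classify_sbs(m$ref, m$alt, m$context5, m$context3),
      SBS288 = {
        strand <- if ("strand" %in% names(m)) m$strand else
          rep("unknown", nrow(m))
        classify_sbs288(m$ref, m$alt, m$context5, m$context3, strand)
      },
      DBS78  = classify_dbs(m$ref, m$alt),
      ID83   = classify_indel(m$ref, m$alt, m$context5, m$context3)
    )
  }
  n_unclassifiable <- sum(is.na(labels))
  ok <- !is.na(labels)
  samples <- unique(as.character(m$sample_id))
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    samples <- c(sample_ids, setdiff(samples, sample_ids))
  }
  counts <- matrix(0L, nrow = length(schema$channels),
                   ncol = length(samples),
                   dimnames = list(schema$channels, samples))
  if (any(ok)) {
    tab <- table(factor(labels[ok], levels = schema$channels),
                 factor(as.character(m$sample_id)[ok], levels = samples))
    counts[] <- counts + as.integer(tab)
  }
  structure(list(
    schema = schema,
    sample_ids = samples,
    counts = counts,
    log = list(n_input = nrow(muts),
               n_classified = sum(ok),
               n_skipped_type = n_skipped_type,
               n_unclassifiable = n_unclassifiable)
  ), class = "catalogue_matrix")
}

#' @export
print.catalogue_matrix <- function(x, ...) {
  cat("<catalogue_matrix>", x$schema$name, ":",
      nrow(x$counts), "channels x", ncol(x$counts), "samples;",
      sum(x$counts), "mutations\n")
  invisible(x)
}

#' Collapse an SBS-96 catalogue to the six primary substitution classes
#'
#' @param cat an SBS-96 \code{catalogue_matrix} or bare counts matrix with
#'   SBS-96 rownames.
#' @return 6 x samples matrix of class proportions (C>A, C>G, C>T, T>A,
#'   T>C, T>G); columns of zero-count samples are \code{NA} and flagged in
#'   the \code{"undefined"} attribute.
#' @export
six_class_profile <- function(cat) {
  counts <- if (inherits(cat, "catalogue_matrix")) cat$counts else cat
  stopifnot(nrow(counts) == 96L)
  cls <- sub("^.\\[(.>.)\\].$", "\\1", rownames(counts))
  agg <- rowsum(counts, cls)
  agg <- agg[SBS_CLASSES, , drop = FALSE]
  totals <- colSums(agg)
  prop <- sweep(agg, 2, totals, "/")
  undefined <- totals == 0
  prop[, undefined] <- NA_real_
  attr(prop, "undefined") <- colnames(counts)[undefined]
  prop
}

#' Write / read a catalogue as SigProfiler-style TSV
#'
#' First column \code{MutationType} carries the channel labels; one
#' tab-separated column per sample. The round trip is exact.
#'
#' @param cat a \code{catalogue_matrix}.
#' @param path file path (".gz" supported).
#' @export
write_catalogue <- function(cat, path) {
  df <- data.frame(MutationType = rownames(cat$counts),
                   cat$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @param schema schema name or object; inferred from row count when NULL.
#' @export
read_catalogue <- function(path, schema = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  labels <- df[[1]]
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- labels
  if (is.null(schema)) {
    schema <- switch(as.character(nrow(counts)),
                     "96" = "SBS96", "288" = "SBS288",
                     "78" = "DBS78", "83" = "ID83",
                     stop("read_catalogue: cannot infer schema from ",
                          nrow(counts), " rows"))
  }
  if (is.character(schema)) schema <- channel_schema(schema)
  counts <- counts[schema$channels, , drop = FALSE]
  structure(list(schema = schema, sample_ids = colnames(counts),
                 counts = counts,
                 log = list(n_input = sum(counts),
                            n_classified = sum(counts),
                            n_skipped_type = 0L, n_unclassifiable = 0L)),
            class = "catalogue_matrix")
}

#' Read / write signature profiles in COSMIC-dialect CSV
#'
#' First column \code{Type} holds channel labels, remaining columns one
#' signature each (column-stochastic profiles).
#'
#' @param path CSV path.
#' @param schema optional schema (inferred from row count when NULL).
#' @return channels x signatures numeric matrix.
#' @export
read_signatures <- function(path, schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.null(schema)) {
    if (is.character(schema)) schema <- channel_schema(schema)
    m <- m[schema$channels, , drop = FALSE]
  }
  m
}

#' @rdname read_signatures
#' @param sigs channels x signatures matrix with rownames.
#' @export
write_signatures <- function(sigs, path) {
  df <- data.frame(Type = rownames(sigs), sigs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read somatic mutations from a minimal VCF 4.x file
#'
#' Parses CHROM, POS, REF, ALT from a (possibly gzipped) VCF. Multi-allelic
#' ALT entries are split into one record each. Sequence context is not
#' present in a plain VCF; supply it via \code{context_fun} (e.g. a
#' FASTA-backed provider) or leave empty for downstream filling.
#'
#' @param path VCF path.
#' @param sample_id sample identifier attached to every record.
#' @param context_fun optional \code{function(chrom, pos, ref)} returning a
#'   list with \code{context5} and \code{context3} strings.
#' @return data frame of mutation records.
#' @export
read_vcf_mutations <- function(path, sample_id, context_fun = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), context5 = character(0),
                      context3 = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  ref <- vapply(parts, `[[`, "", 4L)
  alt0 <- vapply(parts, `[[`, "", 5L)
  alts <- strsplit(alt0, ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep(seq_along(lines), nalt)
  out <- data.frame(sample_id = sample_id, chrom = chrom[idx],
                    pos = pos[idx], ref = ref[idx],
                    alt = unlist(alts), stringsAsFactors = FALSE)
  if (!is.null(context_fun)) {
    ctx <- Map(context_fun, out$chrom, out$pos, out$ref)
    out$context5 <- vapply(ctx, `[[`, "", "context5")
    out$context3 <- vapply(ctx, `[[`, "", "context3")
  } else {
    out$context5 <- ""
    out$context3 <- ""
  }
  out
}

#' FASTA-backed sequence-context provider
#'
#' Loads a (small) FASTA file into memory and returns a function usable as
#' \code{context_fun} in [read_vcf_mutations()], yielding \code{flank} bases
#' of 5' and 3' context around a variant.
#'
#' @param fasta_path FASTA file.
#' @param flank number of bases each side (default 10).
#' @return \code{function(chrom, pos, ref)}.
#' @export
fasta_context_provider <- function(fasta_path, flank = 10L) {
  lines <- readLines(fasta_path)
  hdr <- grepl("^>", lines)
  id <- sub("^>(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  names(seqs) <- id
  function(chrom, pos, ref) {
    s <- seqs[[as.character(chrom)]]
    if (is.null(s)) stop("fasta_context_provider: unknown contig ", chrom)
    obs <- substr(s, pos, pos + nchar(ref) - 1L)
    if (obs != ref)
      stop("fasta_context_provider: REF mismatch at ", chrom, ":", pos)
    list(context5 = substr(s, max(1L, pos - flank), pos - 1L),
         context3 = substr(s, pos + nchar(ref),
                           min(nchar(s), pos + nchar(ref) + flank - 1L)))
  }
}
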