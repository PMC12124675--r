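# Domain types and readers for the formats the pipeline touches.
#
# Coordinate convention: every interval held in memory is 0-based half-open
# (BED convention).  VCF positions are 1-based on ingest and egress only.

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open \code{[start, end)}, the BED convention
#' used throughout the package.
#'
#' @param chrom chromosome names (non-empty strings).
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions; must exceed \code{start}.
#' @param ... further equal-length columns carried through unchanged.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end} and any extras.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the invariants of the internal interval representation:
#' non-empty chromosome names, \code{start >= 0} and \code{end > start}.
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param what label used in error messages.
#' @return \code{x}, invisibly.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop(what, ": chromosome names must be non-empty")
  if (any(!is.finite(x$start) | !is.finite(x$end)))
    stop(what, ": non-finite coordinates")
  if (any(x$start < 0))
    stop(what, ": start must be >= 0")
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop(what, ": end <= start at row ", bad[1L])
  invisible(x)
}

# IRanges live on 1-based closed coordinates; shift on the way in/out.
as_iranges <- function(x) {
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

iranges_to_df <- function(ir, chrom = "chrY") {
  data.frame(chrom = chrom,
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

#' Read a BED file
#'
#' Reads a 3+ column tab-separated BED file into the internal 0-based
#' half-open interval table.  Extra columns are preserved in file order.
#'
#' @param path path to an (uncompressed) BED file.
#' @param col_names optional names for columns beyond the first three.
#' @return interval \code{data.frame}; zero rows for an empty file.
#' @export
read_bed <- function(path, col_names = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), numeric(), numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 tab-separated fields")
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
         " in ", path, ": non-numeric coordinates")
  df <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                   start = start, end = end, stringsAsFactors = FALSE)
  extra <- max(nf) - 3L
  if (extra > 0L) {
    for (j in seq_len(extra)) {
      vals <- vapply(parts, function(p) if (length(p) >= j + 3L) p[[j + 3L]] else NA_character_, "")
      nm <- if (!is.null(col_names) && length(col_names) >= j) col_names[j] else paste0("V", j + 3L)
      df[[nm]] <- vals
    }
  }
  validate_intervals(df, what = paste0("BED file ", path))
  df
}

#' Write a BED file
#'
#' Inverse of [read_bed()]: tab-separated, no header, no quoting, integer
#' coordinates.
#'
#' @param x interval table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  out <- x
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize a set of mask intervals
#'
#' Sorts and merges overlapping or bookended intervals per chromosome,
#' yielding the canonical representation of a callability mask.
#'
#' @param x interval table.
#' @return interval table, sorted, with no two intervals overlapping or
#'   touching on the same chromosome.
#' @export
normalize_mask <- function(x) {
  validate_intervals(x, "mask")
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end")])
  pieces <- lapply(split(x, x$chrom), function(part) {
    iranges_to_df(IRanges::reduce(as_iranges(part)), chrom = part$chrom[1L])
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read haploid variant records from a minimal VCF
#'
#' Ingests a VCF v4.x file (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT
#' plus sample genotype columns) into one record per sample x ALT allele
#' with a haploid 0/1 genotype.  Multiallelic sites are split.  A diploid
#' genotype on the haploid Y is tolerated: the first allele is taken and a
#' warning is emitted.
#'
#' @param path path to an uncompressed VCF file.
#' @return \code{data.frame} with columns \code{sample_id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}, \code{genotype} (0/1).
#' @export
read_variants <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-row VCF drops to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  samples <- colnames(gt)
  out <- vector("list", nrow(fix))
  warned <- FALSE
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    g <- gt[i, , drop = TRUE]
    g[is.na(g)] <- "."
    ploid <- grepl("[/|]", g)
    if (any(ploid)) {
      if (!warned) {
        warning("diploid genotypes on haploid chromosome; taking first allele")
        warned <- TRUE
      }
      g[ploid] <- vapply(strsplit(g[ploid], "[/|]"), `[[`, "", 1L)
    }
    gi <- suppressWarnings(as.integer(g))
    rows <- lapply(seq_along(alts), function(a) {
      data.frame(sample_id = samples,
                 chrom = fix$CHROM[i],
                 pos = as.numeric(fix$POS[i]),
                 ref = fix$REF[i],
                 alt = alts[a],
                 genotype = as.integer(!is.na(gi) & gi == a),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter variant records to a callability mask
#'
#' Keeps exactly the records whose (1-based) position falls inside the
#' normalized mask under the half-open convention, i.e. whose 0-based
#' position \code{pos - 1} lies in some \code{[start, end)} mask interval.
#'
#' @param variants output of [read_variants()] (needs \code{chrom},
#'   \code{pos}).
#' @param mask interval table; normalized internally.
#' @return the surviving rows of \code{variants}.
#' @export
filter_to_mask <- function(variants, mask) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  mask <- normalize_mask(mask)
  if (nrow(variants) == 0L || nrow(mask) == 0L)
    return(variants[integer(0L), , drop = FALSE])
  keep <- rep(FALSE, nrow(variants))
  for (chr in unique(variants$chrom)) {
    m <- mask[mask$chrom == chr, , drop = FALSE]
    if (nrow(m) == 0L) next
    idx <- which(variants$chrom == chr)
    p0 <- variants$pos[idx] - 1  # 0-based
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(start = as.integer(p0) + 1L, width = 1L),
      as_iranges(m))
    keep[idx[S4Vectors::queryHits(hit)]] <- TRUE
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a sample metadata table
#'
#' TSV with header; requires \code{sample_id} and \code{ancestry}.  When an
#' \code{isup} grade column is present, \code{risk} is (re)derived as
#' \code{HRPCa} for grade >= 3 and \code{LRPCa} below.
#'
#' @param path path to the TSV file.
#' @return samples \code{data.frame}.
#' @export
read_samples <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("sample_id", "ancestry") %in% names(df)))
  if ("isup" %in% names(df))
    df$risk <- ifelse(df$isup >= 3, "HRPCa", "LRPCa")
  df
}

#' Read a run configuration
#'
#' Reads a YAML configuration file and merges it over a list of defaults
#' (shallow merge; names present in the file win).
#'
#' @param path YAML file path, or \code{NULL} for defaults only.
#' @param defaults named list of default values.
#' @return named list.
#' @export
read_config <- function(path = NULL, defaults = list()) {
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  cfg
}
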