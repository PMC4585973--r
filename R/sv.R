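#' Construct a table of structural-variant records
#'
#' A structural variant here is a deletion or insertion of at least
#' `sv_min_size` (50 bp by default for gold-set admission; the constructor
#' itself only requires size >= 1 so sub-threshold events can be filtered
#' explicitly). Coordinates are 0-based half-open: a DEL spans
#' `[start, end)` with `size = end - start`; an INS is anchored at a single
#' point (`end == start`) and, when the inserted sequence is known,
#' `size == nchar(inserted_seq)`.
#'
#' @param chrom,start,end,svtype Parallel vectors; `svtype` is "DEL"/"INS".
#' @param size Event sizes in bp; derived from coordinates/sequence if `NA`.
#' @param inserted_seq Inserted sequence for INS records (`NA` if unknown).
#' @param sources Comma-separated provenance labels.
#' @param validations Comma-separated validation labels (subset of
#'   KNOWN_DB, JUNCTION, READPAIR plus any registered extras).
#' @param tier One of "GOLD", "PASS", "NOTVAL", "UNSET".
#' @return data.frame with the columns above plus a stable `id`.
#' @export
sv_records <- function(chrom = character(), start = integer(),
                       end = integer(), svtype = character(),
                       size = NA_integer_, inserted_seq = NA_character_,
                       sources = "", validations = "", tier = "UNSET") {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), svtype = as.character(svtype),
                   size = rep_len(as.integer(size), n),
                   inserted_seq = rep_len(as.character(inserted_seq), n),
                   sources = rep_len(as.character(sources), n),
                   validations = rep_len(as.character(validations), n),
                   tier = rep_len(as.character(tier), n),
                   stringsAsFactors = FALSE)
  if (n == 0L) {
    df$id <- character(0)
    return(df)
  }
  if (any(!df$svtype %in% c("DEL", "INS")))
    stop("svtype must be DEL or INS")
  del <- df$svtype == "DEL"
  if (any(del & df$start >= df$end)) stop("DEL requires start < end")
  if (any(!del & df$start != df$end)) stop("INS requires end == start")
  fill <- del & is.na(df$size)
  df$size[fill] <- df$end[fill] - df$start[fill]
  fill <- !del & is.na(df$size) & !is.na(df$inserted_seq)
  df$size[fill] <- nchar(df$inserted_seq[fill])
  if (any(is.na(df$size))) stop("INS without inserted_seq needs explicit size")
  if (any(del & df$size != df$end - df$start))
    stop("DEL size must equal end - start")
  ins_seq <- !del & !is.na(df$inserted_seq)
  if (any(df$size[ins_seq] != nchar(df$inserted_seq[ins_seq])))
    stop("INS size must equal nchar(inserted_seq) when the sequence is known")
  if (any(df$size < 1L)) stop("size must be >= 1")
  df$id <- sprintf("%s_%d_%s_%d", df$chrom, df$start, df$svtype, df$size)
  df
}

#' @keywords internal
empty_svs <- function() sv_records()

#' Sort SV records by (chrom, start, end)
#' @param x SV data.frame.
#' @return Sorted SV data.frame.
#' @export
sort_svs <- function(x) x[order(x$chrom, x$start, x$end, x$svtype), ,
                          drop = FALSE]

#' Filter SV records to a minimum size
#' @param x SV data.frame.
#' @param min_size Smallest event size kept (bp).
#' @return Filtered SV data.frame.
#' @export
filter_sv_size <- function(x, min_size = 50L) {
  x[x$size >= min_size, , drop = FALSE]
}

# label-set helpers: comma-joined strings used for sources/validations
split_labels <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
}

join_labels <- function(v) paste(sort(unique(v)), collapse = ",")

add_label <- function(s, lab) {
  join_labels(c(split_labels(s), lab))
}

n_labels <- function(s) {
  vapply(s, function(x) length(split_labels(x)), integer(1), USE.NAMES = FALSE)
}

#' Reciprocal overlap between two intervals
#'
#' `min(overlap/len_a, overlap/len_b)`; 0 when disjoint.
#'
#' @param s1,e1,s2,e2 Interval coordinates (vectors recycle).
#' @return Numeric vector of reciprocal-overlap fractions.
#' @export
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ov <- pmax(ov, 0)
  len1 <- e1 - s1
  len2 <- e2 - s2
  ifelse(len1 <= 0 | len2 <= 0, 0, pmin(ov / len1, ov / len2))
}
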