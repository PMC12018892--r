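#' Locate the four AT-repeat loci in a control-region amplicon
#'
#' Scans the forward strand of the ~250 bp 3' control-region amplicon for
#' maximal runs of the "AT" dimer and returns the four qualifying runs in 5'
#' to 3' order. Runs shorter than `min_run` dimers are ignored. No
#' flanking-motif anchoring is attempted by default, so the input must be the
#' amplicon (or a fragment) in sequencing orientation.
#'
#' @param sequence a single DNA string.
#' @param min_run minimum number of AT dimers for a run to count as a locus.
#' @return Data frame with one row per locus: `locus`, `start`, `end`
#'   (0-based half-open span) and `count` (number of AT dimers).
#' @export
segment_at_loci <- function(sequence, min_run = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_up <- toupper(sequence)
  if (grepl("[^ACGTN]", seq_up)) {
    stop("sequence contains non-nucleotide characters")
  }
  m <- gregexpr("(?:AT)+", seq_up, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    stop("segmentation error: 0 AT-repeat runs of length >= ", min_run,
         " found (expected 4)")
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  counts <- lens %/% 2L
  keep <- counts >= min_run
  if (sum(keep) != 4L) {
    stop("segmentation error: ", sum(keep), " AT-repeat runs of length >= ",
         min_run, " found (expected 4); run lengths: ",
         paste(counts[keep], collapse = ", "))
  }
  starts <- starts[keep]
  counts <- counts[keep]
  data.frame(
    locus = 1:4,
    start = starts - 1L,
    end = starts - 1L + counts * 2L,
    count = counts
  )
}

#' Four-number barcode from repeat counts
#'
#' @param counts integer vector of four non-negative AT-repeat counts.
#' @return Barcode string, e.g. `"6-8-8-4"`.
#' @export
mtstr_barcode <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0L)) {
    stop("'counts' must be four non-negative integers")
  }
  paste(counts, collapse = "-")
}

#' Parse a four-number barcode back into repeat counts
#' @param barcode barcode string such as `"6-8-8-4"`.
#' @return Integer vector of length 4.
#' @export
parse_barcode <- function(barcode) {
  stopifnot(is.character(barcode), length(barcode) == 1L)
  counts <- suppressWarnings(as.integer(strsplit(barcode, "-", fixed = TRUE)[[1L]]))
  if (length(counts) != 4L || anyNA(counts)) {
    stop("malformed barcode: ", barcode)
  }
  counts
}

#' Haplotype a sequence into its mtSTR barcode
#'
#' Convenience wrapper: [segment_at_loci()] then [mtstr_barcode()].
#'
#' @inheritParams segment_at_loci
#' @return An `mtstr_haplotype` object (non-heteroplasmic).
#' @export
mtstr_type <- function(sequence, min_run = 3L) {
  counts <- segment_at_loci(sequence, min_run = min_run)$count
  new_mtstr_haplotype(counts, heteroplasmic = FALSE, minor_counts = NULL)
}

new_mtstr_haplotype <- function(counts, heteroplasmic, minor_counts) {
  structure(
    list(
      repeat_counts = as.integer(counts),
      barcode = mtstr_barcode(counts),
      heteroplasmic = heteroplasmic,
      minor_counts = if (!is.null(minor_counts)) as.integer(minor_counts),
      minor_barcode = if (!is.null(minor_counts)) mtstr_barcode(minor_counts)
    ),
    class = "mtstr_haplotype"
  )
}

#' @export
print.mtstr_haplotype <- function(x, ...) {
  cat("<mtstr_haplotype>", x$barcode)
  if (isTRUE(x$heteroplasmic)) {
    cat(" (heteroplasmic; minor", x$minor_barcode, ")")
  }
  cat("\n")
  invisible(x)
}

#' Resolve heteroplasmy by major peak height
#'
#' Given, for each of the four loci, candidate repeat counts with their
#' electropherogram peak heights, takes the highest peak per locus as the
#' major allele. A locus is heteroplasmic when a second candidate reaches at
#' least `noise_floor` times the major peak; the strongest such runner-up is
#' recorded as the minor allele. An exact tie for the major peak is an
#' ambiguity error, never broken silently.
#'
#' @param peaks list of four named numeric vectors; names are candidate
#'   repeat counts, values are positive peak heights.
#' @param noise_floor fraction of the major peak height below which minor
#'   peaks are treated as noise.
#' @return An `mtstr_haplotype` with `heteroplasmic` flag and, when set,
#'   `minor_counts`/`minor_barcode`.
#' @export
call_major_haplotype <- function(peaks, noise_floor = 0.2) {
  if (!is.list(peaks) || length(peaks) != 4L) {
    stop("'peaks' must be a list of four named height vectors")
  }
  major <- integer(4L)
  minor <- integer(4L)
  het <- logical(4L)
  for (i in 1:4) {
    h <- peaks[[i]]
    if (length(h) < 1L || is.null(names(h)) || any(h <= 0)) {
      stop("locus ", i, ": candidates must be a named vector of positive heights")
    }
    top <- max(h)
    if (sum(h == top) > 1L) {
      stop("ambiguity error: exact peak-height tie at locus ", i,
           " between counts ", paste(names(h)[h == top], collapse = ", "))
    }
    major[i] <- as.integer(names(h)[which.max(h)])
    minor[i] <- major[i]
    rest <- h[-which.max(h)]
    if (length(rest) && max(rest) >= noise_floor * top) {
      het[i] <- TRUE
      minor[i] <- as.integer(names(rest)[which.max(rest)])
    }
  }
  new_mtstr_haplotype(
    major,
    heteroplasmic = any(het),
    minor_counts = if (any(het)) minor
  )
}

#' Haplotype inventory across population categories
#'
#' @param categories named list of character vectors of barcodes, e.g.
#'   Israeli nests, Israeli stranded, Turkey/Cyprus nests.
#' @return An object of class `haplotype_inventory`.
#' @export
haplotype_inventory <- function(categories) {
  if (!is.list(categories) || length(categories) < 1L ||
      is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("'categories' must be a non-empty named list of barcode vectors")
  }
  categories <- lapply(categories, function(x) sort(unique(as.character(x))))
  structure(categories, class = "haplotype_inventory")
}

#' Set algebra on a haplotype inventory
#'
#' Computes per-category totals, all pairwise (and higher-order)
#' intersections, the union, and each category's share of the union as a
#' percentage rounded to the nearest integer.
#'
#' @param inv a [haplotype_inventory()] (or the named list it wraps).
#' @return A list with `totals`, `intersections` (named by
#'   `"a&b"` style keys), `union_size`, and `percent_of_union`.
#' @export
inventory_overlap <- function(inv) {
  if (!inherits(inv, "haplotype_inventory")) inv <- haplotype_inventory(inv)
  cats <- names(inv)
  all_bc <- sort(unique(unlist(inv)))
  totals <- vapply(inv, length, integer(1L))
  inter <- list()
  if (length(cats) >= 2L) {
    for (k in 2:length(cats)) {
      for (idx in as.data.frame(combn(length(cats), k))) {
        key <- paste(cats[idx], collapse = "&")
        inter[[key]] <- length(Reduce(intersect, inv[idx]))
      }
    }
  }
  pct <- round(100 * totals / length(all_bc))
  list(
    totals = totals,
    intersections = unlist(inter),
    union_size = length(all_bc),
    percent_of_union = pct
  )
}
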