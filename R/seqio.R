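DNA_BASES <- c("A", "C", "G", "T")

# integer codes A=1, C=2, G=3, T=4; N -> NA. Errors on anything else.
seq_to_codes <- function(seq, id = "<sequence>") {
  v <- utf8ToInt(toupper(seq))
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  if (any(v > 128L) || anyNA(lut[v])) {
    bad <- unique(intToUtf8(v[v > 128L | is.na(lut[pmin(v, 128L)])], multiple = TRUE))
    stop("sequence '", id, "' contains non-IUPAC characters (beyond ACGTN): ",
         paste(bad, collapse = ", "))
  }
  codes <- lut[v]
  codes[codes == 5L] <- NA_integer_
  codes
}

codes_to_seq <- function(codes) {
  out <- c(DNA_BASES, "N")[ifelse(is.na(codes), 5L, codes)]
  paste(out, collapse = "")
}

#' Read a FASTA file into a labeled sequence table
#'
#' Reads a (possibly multi-line, case-insensitive) FASTA file and returns one
#' row per record with the sequence uppercased. The class label is assigned by
#' the caller: `+1` for foreground sets, `-1` for background sets.
#'
#' @param path Path to a FASTA file.
#' @param label Class label attached to every record, `+1` (foreground),
#'   `-1` (background) or `NA` if not yet decided.
#' @return A `data.frame` with columns `id`, `seq`, `label`, record order
#'   preserved.
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  labeled_sequences(ids, toupper(as.character(set)), label)
}

#' Construct a labeled sequence table
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of DNA sequences over `ACGTN` (any case).
#' @param label Scalar or vector of labels in `{+1, -1, NA}`.
#' @return A `data.frame` with columns `id`, `seq` (uppercased), `label`.
#' @export
labeled_sequences <- function(ids, seqs, label = NA_integer_) {
  stopifnot(length(ids) == length(seqs))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < 1L)) stop("empty sequence in input")
  for (i in seq_along(seqs)) seq_to_codes(seqs[i], ids[i])  # validates alphabet
  if (!all(is.na(label)) && !all(label %in% c(-1L, 1L)))
    stop("labels must be +1 (foreground) or -1 (background)")
  data.frame(id = as.character(ids), seq = seqs,
             label = rep_len(as.integer(label), length(seqs)),
             stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement; `N` maps to `N`.
#'
#' @param seq A DNA string over `ACGTN` (any case).
#' @return The reverse-complemented string, uppercase.
#' @export
reverse_complement <- function(seq) {
  seq_to_codes(seq)  # validates the alphabet (errors beyond ACGTN)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' One-hot encode a DNA site
#'
#' Encodes each base as a 4-dimensional indicator, `A=(1,0,0,0)`,
#' `C=(0,1,0,0)`, `G=(0,0,1,0)`, `T=(0,0,0,1)`, and concatenates the blocks
#' into a binary vector of length `4*l` (block `i` describes position `i`).
#'
#' @param site A DNA string containing no `N`.
#' @return Numeric binary vector of length `4 * nchar(site)` with exactly one
#'   1 per block.
#' @export
one_hot_encode <- function(site) {
  codes <- seq_to_codes(site)
  if (anyNA(codes)) stop("site contains N; only unambiguous sites can be encoded")
  l <- length(codes)
  x <- numeric(4L * l)
  x[4L * (seq_len(l) - 1L) + codes] <- 1
  x
}

#' Decode a one-hot encoding back to a DNA string
#'
#' @param x Binary vector of length `4*l` with exactly one 1 per 4-block.
#' @return The DNA string of length `l`.
#' @export
decode_one_hot <- function(x) {
  if (length(x) %% 4L != 0L) stop("encoding length is not a multiple of 4")
  m <- matrix(x, nrow = 4L)
  if (!all(colSums(m) == 1) || !all(x %in% c(0, 1)))
    stop("not a one-hot encoding: each 4-block must contain exactly one 1")
  paste(DNA_BASES[apply(m, 2L, which.max)], collapse = "")
}

# internal: one-hot rows for a matrix of site codes (nwin x l)
encode_site_rows <- function(sites) {
  n <- nrow(sites); l <- ncol(sites)
  X <- matrix(0, n, 4L * l)
  off <- rep(4L * (seq_len(l) - 1L), each = n)
  X[cbind(rep(seq_len(n), l), off + as.vector(sites))] <- 1
  X
}

#' Build the window bag of a sequence
#'
#' Slides an `l`-length window over the sequence and its reverse complement
#' and collects every window as a candidate binding site. Windows containing
#' `N` are dropped. Each window keeps forward-strand coordinates (0-based
#' start) so that site calls can be emitted later; minus-strand windows carry
#' the forward-strand start of the region they cover. Windows are ordered
#' forward strand first, then by ascending offset, which is also the
#' deterministic tie-break order used throughout.
#'
#' @param id Sequence identifier.
#' @param seq DNA string over `ACGTN`.
#' @param l Motif (window) length.
#' @param label Class label (`+1`/`-1`/`NA`).
#' @param exclude Optional two-column matrix of 0-based half-open `[start,end)`
#'   intervals; windows overlapping any interval are dropped (used by masking).
#' @return An object of class `wsmd_bag`: a list with `id`, `label`, `n`
#'   (sequence length), `l`, `offset`, `strand`, and the `nwin x l` integer
#'   matrix `sites` of base codes.
#' @export
make_window_bag <- function(id, seq, l, label = NA_integer_, exclude = NULL) {
  codes <- seq_to_codes(seq, id)
  n <- length(codes)
  if (n < l) stop("sequence '", id, "' is shorter (", n, ") than the window length ", l)
  starts <- 0:(n - l)                                  # 0-based
  pos <- outer(starts + 1L, seq_len(l) - 1L, `+`)      # 1-based index matrix
  fwd <- matrix(codes[pos], nrow = length(starts))
  rev <- matrix(5L - codes[pos[, l:1, drop = FALSE]], nrow = length(starts))
  sites <- rbind(fwd, rev)
  offset <- c(starts, starts)
  strand <- rep(c("+", "-"), each = length(starts))
  keep <- !apply(is.na(sites), 1L, any)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    for (r in seq_len(nrow(exclude))) {
      keep <- keep & (offset + l <= exclude[r, 1L] | offset >= exclude[r, 2L])
    }
  }
  structure(list(id = id, label = label, n = n, l = l,
                 offset = offset[keep], strand = strand[keep],
                 sites = sites[keep, , drop = FALSE]),
            class = "wsmd_bag")
}

#' Build window bags for a sequence table
#'
#' @param seqs A `data.frame` as returned by [read_fasta()] or
#'   [labeled_sequences()].
#' @param l Window length.
#' @param exclude Optional named list (by sequence id position) of interval
#'   matrices passed to [make_window_bag()].
#' @return List of `wsmd_bag` objects, one per row of `seqs`.
#' @export
make_window_bags <- function(seqs, l, exclude = NULL) {
  lapply(seq_len(nrow(seqs)), function(i) {
    make_window_bag(seqs$id[i], seqs$seq[i], l, seqs$label[i],
                    exclude = if (is.null(exclude)) NULL else exclude[[i]])
  })
}

#' @export
print.wsmd_bag <- function(x, ...) {
  cat("window bag '", x$id, "': ", length(x$offset), " windows of length ",
      x$l, " (sequence length ", x$n, ")\n", sep = "")
  invisible(x)
}

# internal: substring of the forward sequence covered by window i of a bag,
# as scanned (minus-strand windows are reverse-complemented)
bag_window_string <- function(bag, i) {
  codes_to_seq(bag$sites[i, ])
}
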