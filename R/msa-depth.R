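# Effective sequence count (Neff) of a multiple sequence alignment.

#' Read an aligned FASTA / A2M file as an MSA
#'
#' @param path aligned FASTA file.
#' @return list of class `na_msa` with `names` and `rows` (upper-case
#'   aligned sequences of equal length; `.` gaps normalised to `-`).
#' @export
read_msa <- function(path) {
  fa <- bio3d::read.fasta(path)
  rows <- toupper(apply(fa$ali, 1, paste, collapse = ""))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  new_msa(rows, names = rownames(fa$ali))
}

#' Construct an MSA object
#'
#' @param rows character vector of aligned sequences (equal length).
#' @param names optional sequence names.
#' @export
new_msa <- function(rows, names = NULL) {
  rows <- toupper(rows)
  if (!length(rows)) stop("MSA needs at least one row")
  if (length(unique(nchar(rows))) != 1) stop("MSA rows differ in length")
  structure(list(names = names %||% paste0("seq", seq_along(rows)),
                 rows = unname(rows)), class = "na_msa")
}

# rows as a character matrix with T folded into U and N masked
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, ""))
  m[m == "T"] <- "U"
  m
}

#' Pairwise identity of two aligned rows
#'
#' Columns gapped in both sequences are ignored; a gap against a residue
#' counts as a mismatch, and `N` matches nothing.
#'
#' @param a,b aligned sequences of equal length.
#' @return identity fraction, or `NA` when every column is gapped in both.
#' @export
pairwise_identity <- function(a, b) {
  m <- msa_matrix(new_msa(c(a, b)))
  keep <- !(m[1, ] == "-" & m[2, ] == "-")
  if (!any(keep)) return(NA_real_)
  x <- m[1, keep]; y <- m[2, keep]
  mean(x == y & x != "-" & x != "N")
}

#' Effective number of sequences in an MSA
#'
#' Each sequence is weighted by the number of sequences in the alignment
#' (including itself) with pairwise identity strictly above the threshold;
#' Neff is the sum of inverse weights. The include-self convention keeps
#' every weight >= 1, matching standard AlphaFold2/trRosettaRNA practice.
#'
#' @param msa an `na_msa` (or character vector of aligned rows).
#' @param identity_threshold redundancy threshold (default 0.8).
#' @return Neff, between 1 and the number of rows.
#' @export
neff <- function(msa, identity_threshold = 0.8) {
  if (is.character(msa)) msa <- new_msa(msa)
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n == 1) return(1)
  w <- rep(1L, n)
  res <- m != "-"
  match_ok <- res & m != "N"
  for (i in seq_len(n - 1)) {
    mi <- m[i, ]
    for (j in (i + 1):n) {
      keep <- res[i, ] | res[j, ]
      nk <- sum(keep)
      if (nk == 0) next
      idt <- sum(mi[keep] == m[j, keep] & match_ok[i, keep]) / nk
      if (idt > identity_threshold) { w[i] <- w[i] + 1L; w[j] <- w[j] + 1L }
    }
  }
  sum(1 / w)
}
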