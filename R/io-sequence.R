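AA1 <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

#' Sequence record with explicit full-length numbering
#'
#' Construct numbering is explicit: `first_residue_number` gives the
#' full-length position of the first residue so that profiles from
#' different constructs of the same protein can be aligned without
#' implicit offsets.
#'
#' @param id Record identifier.
#' @param residues One-letter amino-acid string (20 letters plus `X`).
#' @param first_residue_number 1-based number of the first residue in the
#'   full-length protein.
#' @return Object of class `sequence_record` with fields `id`, `residues`,
#'   `first_residue_number` and `numbers` (per-residue numbering).
#' @export
sequence_record <- function(id, residues, first_residue_number = 1L) {
  residues <- toupper(residues)
  stopifnot(nchar(residues) >= 1, first_residue_number >= 1)
  letters_vec <- strsplit(residues, "")[[1]]
  bad <- which(!letters_vec %in% c(AA1, "X"))
  if (length(bad))
    stop(sprintf("illegal residue character '%s' at position %d",
                 letters_vec[bad[1]], bad[1]))
  numbers <- seq.int(first_residue_number, length.out = length(letters_vec))
  structure(list(id = id, residues = residues,
                 first_residue_number = as.integer(first_residue_number),
                 numbers = as.integer(numbers)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("sequence_record '%s': %d residues, numbered %d-%d\n",
              x$id, nchar(x$residues), x$numbers[1],
              x$numbers[length(x$numbers)]))
  invisible(x)
}

#' Read the first record of a FASTA file
#'
#' @param path FASTA file with at least one record.
#' @param first_residue_number Full-length number of the first residue.
#' @return A [sequence_record()]. Lowercase letters are uppercased with a
#'   warning; characters outside the 20-letter alphabet plus `X` raise an
#'   error naming the offending position.
#' @export
read_sequence <- function(path, first_residue_number = 1L) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  seq <- as.character(set[[1]])
  if (grepl("[a-z]", seq)) {
    warning("lowercase residues uppercased in ", basename(path))
    seq <- toupper(seq)
  }
  sequence_record(names(set)[1], seq, first_residue_number)
}

#' Subset the one-letter string of a construct by full-length numbering
#' @param seqrec A [sequence_record()].
#' @param numbers Full-length residue numbers to extract.
#' @return Character vector of one-letter codes (`NA` outside the construct).
#' @export
residue_at <- function(seqrec, numbers) {
  idx <- numbers - seqrec$first_residue_number + 1L
  letters_vec <- strsplit(seqrec$residues, "")[[1]]
  out <- rep(NA_character_, length(numbers))
  ok <- idx >= 1 & idx <= length(letters_vec)
  out[ok] <- letters_vec[idx[ok]]
  out
}
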