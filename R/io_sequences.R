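AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a sequence record
#'
#' @param id accession string (non-empty)
#' @param residues amino-acid string; lowercase letters are uppercased and
#'   `*` stop characters stripped; only the 20 standard letters plus `X` are
#'   accepted afterwards
#' @param description free-text description
#' @return an object of class `seq_record` with fields `id`, `description`,
#'   `residues` and `length`
#' @export
#' @examples
#' seq_record("B8N0E8", "MKTAYIAK")
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L)
    stop("residues must be a single string")
  residues <- gsub("*", "", toupper(residues), fixed = TRUE)
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA_LETTERS, "X"))
  if (length(bad))
    stop("sequence '", id, "' contains non-amino-acid characters: ",
         paste(unique(bad), collapse = ", "))
  structure(list(id = id, description = description, residues = residues,
                 length = nchar(residues)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d aa)%s\n", x$id, x$length,
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

check_unique_ids <- function(seqs) {
  ids <- vapply(seqs, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  ids
}

#' Read amino-acid sequences from a FASTA file
#'
#' Wrapped (multi-line) records are concatenated, lowercase letters
#' uppercased, and `*` stop characters stripped. Record order is preserved.
#' Duplicate ids and characters outside the 20 standard amino acids plus
#' `X`/`*` are errors.
#'
#' @param path path to a FASTA file
#' @return a list of [seq_record()] objects
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L)
    stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- mapply(function(i, d, s) seq_record(i, s, d),
                 ids, desc, as.character(set), SIMPLIFY = FALSE)
  names(seqs) <- NULL
  check_unique_ids(seqs)
  seqs
}

#' Write sequence records to a FASTA file
#'
#' @param seqs list of [seq_record()] objects
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  check_unique_ids(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- vapply(seqs, function(s) {
    if (nzchar(s$description)) paste(s$id, s$description) else s$id
  }, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a 12-column BLAST tabular hit file (outfmt 6)
#'
#' Consumes the output of an upstream homology search; the search itself is
#' outside this package. Columns follow the standard order: query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score.
#'
#' @param path path to a tab-separated hit file; an empty file yields an
#'   empty data frame
#' @return a data frame with columns `query_id`, `subject_id`, `evalue`,
#'   `identity_pct`, `aln_len`
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), identity_pct = numeric(),
                      aln_len = integer(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed BLAST tabular line(s) with fewer than 12 columns: line ",
         paste(which(nf < 12L), collapse = ", "))
  hit <- function(k, as = as.character) vapply(fields, function(f) f[[k]], "")
  out <- data.frame(
    query_id = hit(1), subject_id = hit(2),
    evalue = as.numeric(vapply(fields, `[[`, "", 11L)),
    identity_pct = as.numeric(vapply(fields, `[[`, "", 3L)),
    aln_len = as.integer(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  bad <- which(is.na(out$evalue) | is.na(out$identity_pct) | is.na(out$aln_len) |
                 out$evalue < 0 | out$identity_pct < 0 | out$identity_pct > 100)
  if (length(bad))
    stop("malformed BLAST tabular line(s): line ", paste(bad, collapse = ", "))
  out
}
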