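# FASTA / aligned-FASTA / chemical-shift-table input and output.
#
# Sequence sets are plain data frames with columns `id`, `description`,
# `taxon`, `residues` (one row per record).  Taxonomy is carried as a
# single order-level tag parsed from a `taxon=<Order>` key in the header
# description, which is all the downstream taxonomy-restricted search
# needs.  All coordinates are 1-based and inclusive.

new_seq_set <- function(id = character(), description = character(),
                        taxon = character(), residues = character()) {
  data.frame(id = id, description = description, taxon = taxon,
             residues = residues, stringsAsFactors = FALSE)
}

# Validate residue strings against the canonical alphabet.
# policy "strict": error naming the record and the offending letters.
# policy "mask":   replace offending letters with "X" (which no motif
#                  position, not even "any", will ever match).
apply_residue_policy <- function(residues, ids, policy, extra_allowed = character()) {
  allowed <- c(AA_CANONICAL, extra_allowed)
  bad_rx <- paste0("[^", paste(allowed, collapse = ""), "]")
  for (i in seq_along(residues)) {
    bad <- regmatches(residues[i], gregexpr(bad_rx, residues[i]))[[1]]
    if (length(bad) == 0L) next
    if (policy == "strict") {
      stop(sprintf("non-canonical residue(s) %s in record '%s'",
                   paste(sQuote(unique(bad)), collapse = ", "), ids[i]),
           call. = FALSE)
    }
    residues[i] <- gsub(bad_rx, "X", residues[i])
  }
  residues
}

read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(Biostrings::BStringSet())
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA in '%s': sequence line before any header at line %d",
                 path, nonblank[1]), call. = FALSE)
  }
  Biostrings::readBStringSet(path)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a sequence-set data
#' frame.  Residues are uppercased and `*` stop symbols stripped.  A
#' taxonomic order tag is parsed from a `taxon=<name>` key in the header
#' description when present.
#'
#' @param path Path to a FASTA file.
#' @param policy How to treat non-canonical residue letters:
#'   `"strict"` (default) raises an error naming the record and the
#'   offending characters; `"mask"` replaces them with `"X"`, which never
#'   matches any motif position.
#' @return A data frame with columns `id`, `description`, `taxon`
#'   (`NA` when absent) and `residues`.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 taxon=Brassicales", "SSTSKLLNKVAARASS"), f)
#' read_fasta(f)
read_fasta <- function(path, policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  set <- read_fasta_raw(path)
  if (length(set) == 0L) return(new_seq_set())
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(id))) stop("empty sequence identifier in ", path, call. = FALSE)
  residues <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  residues <- gsub("[[:space:]]", "", residues)
  residues <- apply_residue_policy(residues, id, policy)
  taxon <- vapply(description, function(d) {
    m <- regmatches(d, regexpr("taxon=\\S+", d))
    if (length(m)) sub("^taxon=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  new_seq_set(id, description, taxon, residues)
}

#' Write a sequence set to FASTA
#'
#' Writes 60-column-wrapped FASTA.  A `taxon=<name>` key is appended to
#' the description for records whose `taxon` is set but not already
#' present in the description, so [read_fasta()] round-trips the tag.
#'
#' @param records Sequence-set data frame as returned by [read_fasta()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else rep("", nrow(records))
  taxon <- if ("taxon" %in% names(records)) records$taxon else rep(NA_character_, nrow(records))
  need_tag <- !is.na(taxon) & !grepl("taxon=", desc)
  desc[need_tag] <- trimws(paste(desc[need_tag], paste0("taxon=", taxon[need_tag])))
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All entries must have equal length after parsing; `.` gap characters
#' are normalised to `-`.
#'
#' @inheritParams read_fasta
#' @return An object of class `aligned_set`: a list with elements
#'   `records` (sequence-set data frame whose residues may contain `-`)
#'   and `column_count`.
#' @export
read_alignment <- function(path, policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  set <- read_fasta_raw(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  residues <- gsub(".", "-", residues, fixed = TRUE)
  lens <- nchar(residues)
  if (length(unique(lens)) > 1L) {
    i <- which(lens != lens[1])[1]
    stop(sprintf("ragged alignment: '%s' has %d columns but '%s' has %d",
                 id[1], lens[1], id[i], lens[i]), call. = FALSE)
  }
  residues <- apply_residue_policy(residues, id, policy, extra_allowed = "-")
  taxon <- vapply(description, function(d) {
    m <- regmatches(d, regexpr("taxon=\\S+", d))
    if (length(m)) sub("^taxon=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  aligned_set(new_seq_set(id, description, taxon, residues))
}

#' Construct an aligned set from a sequence-set data frame
#'
#' @param records Sequence-set data frame; residues may contain `-`.
#' @return An `aligned_set` object.
#' @export
aligned_set <- function(records) {
  lens <- nchar(records$residues)
  if (nrow(records) > 0L && length(unique(lens)) > 1L) {
    stop("aligned_set: sequences have unequal lengths", call. = FALSE)
  }
  structure(
    list(records = records,
         column_count = if (nrow(records)) lens[1] else 0L),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d sequences x %d columns\n",
              nrow(x$records), x$column_count))
  invisible(x)
}

#' Remove gap characters from an alignment
#'
#' @param aln An `aligned_set`.
#' @return A sequence-set data frame of the degapped records.
#' @export
degap <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  out <- aln$records
  out$residues <- gsub("-", "", out$residues, fixed = TRUE)
  out
}

#' Write an aligned set to FASTA
#'
#' @param aln An `aligned_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_set"))
  write_fasta(aln$records, path)
}

#' Read an assigned C-alpha chemical-shift table
#'
#' Expects a tab-separated file with a header line naming the columns
#' `residue_index`, `residue_code` and `ca_shift_ppm`.  Optional metadata
#' lines `#temperature_C=<x>` and `#pH=<x>` may precede the header;
#' defaults are 5 degrees C and pH 7.0, the conditions under which the
#' motif peptides are typically recorded.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `shift_table` with the three columns,
#'   plus attributes `temperature_C` and `pH`.  Rows with a missing
#'   shift are dropped with a warning; duplicate or decreasing residue
#'   indices are an error.
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^#", key, "="), "", hit[1])) else default
  }
  temperature_C <- get_meta("temperature_C", 5)
  pH <- get_meta("pH", 7.0)
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  required <- c("residue_index", "residue_code", "ca_shift_ppm")
  if (!all(required %in% names(tab))) {
    stop("shift table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[required]
  tab$ca_shift_ppm <- suppressWarnings(as.numeric(tab$ca_shift_ppm))
  missing <- is.na(tab$ca_shift_ppm)
  if (any(missing)) {
    warning(sprintf("dropping %d row(s) with missing ca_shift_ppm (residue index %s)",
                    sum(missing), paste(tab$residue_index[missing], collapse = ", ")),
            call. = FALSE)
    tab <- tab[!missing, , drop = FALSE]
  }
  if (any(diff(tab$residue_index) <= 0)) {
    i <- which(diff(tab$residue_index) <= 0)[1]
    stop(sprintf("residue_index not strictly increasing at row %d (%d then %d)",
                 i + 1L, tab$residue_index[i], tab$residue_index[i + 1L]),
         call. = FALSE)
  }
  out_of_window <- tab$ca_shift_ppm < 40 | tab$ca_shift_ppm > 75
  if (any(out_of_window)) {
    warning(sprintf("%d C-alpha shift(s) outside the 40-75 ppm sanity window",
                    sum(out_of_window)), call. = FALSE)
  }
  tab$residue_code <- toupper(tab$residue_code)
  rownames(tab) <- NULL
  structure(tab, class = c("shift_table", "data.frame"),
            temperature_C = temperature_C, pH = pH)
}

#' Write a chemical-shift table
#'
#' @param shifts A `shift_table` (or compatible data frame).
#' @param path Output file path.
#' @param temperature_C,pH Metadata written as `#key=value` lines;
#'   default to the table's attributes.
#' @return Invisibly, `path`.
#' @export
write_shift_table <- function(shifts, path,
                              temperature_C = attr(shifts, "temperature_C"),
                              pH = attr(shifts, "pH")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(temperature_C)) writeLines(sprintf("#temperature_C=%g", temperature_C), con)
  if (!is.null(pH)) writeLines(sprintf("#pH=%g", pH), con)
  utils::write.table(as.data.frame(shifts)[c("residue_index", "residue_code", "ca_shift_ppm")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
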