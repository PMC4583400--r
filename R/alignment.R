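#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Characters treated as missing data everywhere downstream (distances, site
# statistics): gaps, N and all IUPAC ambiguity codes.  Only A, C, G, T count.
UNAMBIGUOUS <- c("A", "C", "G", "T")

#' Barcode alignment objects
#'
#' A `barcode_alignment` holds an aligned set of DNA barcode sequences
#' together with parsed specimen labels.  Sequences are stored as an
#' `n x L` character matrix (one row per record, upper case); labels are a
#' tibble with one row per record carrying the raw FASTA header, the parsed
#' species name and the identification level.
#'
#' @param seq_matrix character matrix of single characters, rows named by
#'   record id.
#' @param info tibble with columns `id`, `label`, `species`, `id_level`.
#' @param frame integer in 1:3, the codon position of alignment column 1,
#'   or `NA` if not yet determined.
#'
#' @return An object of class `barcode_alignment` with elements `seq`
#'   (character matrix), `info` (tibble) and `frame`.
#' @seealso [read_fasta()], [detect_frame()]
#' @export
barcode_alignment <- function(seq_matrix, info, frame = NA_integer_) {
  stopifnot(is.matrix(seq_matrix), is.character(seq_matrix))
  if (nrow(seq_matrix) == 0L) stop("alignment must contain at least one record")
  if (anyDuplicated(info$id)) {
    dup <- info$id[duplicated(info$id)][1L]
    stop("duplicate sequence id: ", dup)
  }
  rownames(seq_matrix) <- info$id
  structure(
    list(seq = seq_matrix, info = as_tibble(info), frame = as.integer(frame)),
    class = "barcode_alignment"
  )
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("barcode_alignment: ", nrow(x$seq), " sequences, ", ncol(x$seq),
      " columns, frame ", ifelse(is.na(x$frame), "unset", x$frame), "\n",
      sep = "")
  lv <- table(x$info$id_level)
  cat("  id levels:", paste(names(lv), lv, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.barcode_alignment <- function(x) dim(x$seq)

#' Number of records and columns
#' @param aln a [barcode_alignment()].
#' @return Integer count.
#' @export
n_records <- function(aln) nrow(aln$seq)

#' @rdname n_records
#' @export
n_columns <- function(aln) ncol(aln$seq)

#' Subset an alignment
#'
#' `i` selects records (by position, logical mask or id), `j` selects
#' alignment columns.  The frame is kept only when column 1 is retained as
#' the first column (otherwise it is invalidated to `NA`).
#'
#' @param x a [barcode_alignment()].
#' @param i record index. @param j column index.
#' @param ... ignored.
#' @return A `barcode_alignment`.
#' @export
`[.barcode_alignment` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$seq))
  if (is.character(i)) i <- match(i, x$info$id)
  frame <- x$frame
  if (!missing(j)) {
    jj <- seq_len(ncol(x$seq))[j]
    frame <- if (length(jj) && identical(jj, seq_len(length(jj)))) x$frame else NA_integer_
  } else {
    j <- seq_len(ncol(x$seq))
  }
  barcode_alignment(x$seq[i, j, drop = FALSE], x$info[i, , drop = FALSE], frame)
}

# ---- label parsing ---------------------------------------------------------

# Tokens that mark an informal/group-code identification rather than a
# formal binomial ("Tanytarsus sp.3XL", "Genus cf. something").
GROUP_CODE_RE <- "^(sp|cf|aff|nr)\\.?([0-9A-Za-z].*)?$"

parse_one_label <- function(label, delim, id_field, species_field) {
  fields <- strsplit(label, delim, fixed = TRUE)[[1L]]
  id <- if (length(fields) >= id_field) trimws(fields[id_field]) else trimws(label)
  taxon <- if (length(fields) >= species_field) trimws(fields[species_field]) else ""
  taxon <- gsub("_", " ", taxon)
  tokens <- strsplit(taxon, "[ ]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 2L) {
    list(id = id, species = NA_character_, id_level = "genus_only")
  } else if (any(grepl(GROUP_CODE_RE, tokens[-1L], ignore.case = TRUE))) {
    list(id = id, species = paste(tokens, collapse = " "), id_level = "group_code")
  } else {
    list(id = id, species = paste(tokens, collapse = " "), id_level = "species")
  }
}

#' Label parsing scheme
#'
#' Describes how FASTA headers encode the specimen id and taxon.  The
#' default matches pipe-delimited BOLD-style exports: field 1 is the unique
#' id, field 2 the taxon with underscores for spaces.  Records whose taxon
#' field is missing or a bare genus are flagged `genus_only`; taxa with
#' "sp."/"cf."-style epithets are kept verbatim as distinct `group_code`
#' identifications.
#'
#' @param delim field delimiter (fixed string).
#' @param id_field,species_field 1-based field positions.
#' @return A `label_scheme` list.
#' @export
label_scheme <- function(delim = "|", id_field = 1L, species_field = 2L) {
  structure(list(delim = delim, id_field = as.integer(id_field),
                 species_field = as.integer(species_field)),
            class = "label_scheme")
}

# ---- FASTA I/O -------------------------------------------------------------

#' Read an aligned FASTA file
#'
#' Accepts wrapped or single-line FASTA.  All records must have the same
#' aligned length; ragged input is an error naming the offending record.
#' Species names and identification levels are parsed from headers
#' according to `scheme`, and can later be overridden with [set_labels()].
#' Gaps, `N` and IUPAC ambiguity codes are treated as missing data by all
#' downstream statistics and distances.
#'
#' @param path path to a FASTA file.
#' @param scheme a [label_scheme()].
#' @param frame optional known codon position of column 1 (1, 2 or 3); if
#'   `NA`, set later via [detect_frame()].
#' @return A [barcode_alignment()].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x1|Tanytarsus_mendax", "ACGT", ">x2|Tanytarsus", "ACGA"), fa)
#' aln <- read_fasta(fa)
#' aln$info
#' @export
read_fasta <- function(path, scheme = label_scheme(), frame = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  labels <- sub("^>", "", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    if (starts[k] > ends[k]) return("")
    paste(lines[starts[k]:ends[k]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[ \t]", "", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("ragged alignment: record '", labels[bad], "' has length ", lens[bad],
         " but record 1 has length ", lens[1L])
  }
  parsed <- lapply(labels, parse_one_label, delim = scheme$delim,
                   id_field = scheme$id_field, species_field = scheme$species_field)
  info <- tibble(
    id = vapply(parsed, `[[`, character(1), "id"),
    label = labels,
    species = vapply(parsed, `[[`, character(1), "species"),
    id_level = vapply(parsed, `[[`, character(1), "id_level")
  )
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  barcode_alignment(m, info, frame)
}

#' Write an alignment as single-line FASTA
#'
#' Headers are the original raw labels, so `read_fasta()` then
#' `write_fasta()` round-trips records and their order.
#'
#' @param aln a [barcode_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", aln$info$label)
  out[c(FALSE, TRUE)] <- seqs
  writeLines(out, path)
  invisible(path)
}

#' Override labels from a TSV sheet
#'
#' The sheet must have columns `id`, `species`, `id_level`; rows are matched
#' to records by `id` and replace the header-parsed values.
#'
#' @param aln a [barcode_alignment()].
#' @param sheet a data frame (or path to a TSV file) with the three columns.
#' @return The updated alignment.
#' @export
set_labels <- function(aln, sheet) {
  if (is.character(sheet)) {
    sheet <- utils::read.delim(sheet, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "species", "id_level") %in% names(sheet)))
  i <- match(sheet$id, aln$info$id)
  if (anyNA(i)) stop("label sheet ids not in alignment: ",
                     paste(sheet$id[is.na(i)], collapse = ", "))
  aln$info$species[i] <- as.character(sheet$species)
  aln$info$id_level[i] <- as.character(sheet$id_level)
  aln
}

# ---- lengths and frame -----------------------------------------------------

#' Ungapped sequence lengths
#'
#' Counts, per record, the alignment columns that are neither `-` nor `N`
#' (ambiguity codes other than N still count as sequenced positions here;
#' they are excluded only from state-based statistics).
#'
#' @param aln a [barcode_alignment()].
#' @return Named integer vector.
#' @examples
#' aln <- alignment_from_strings(c(a = "AC-GN"))
#' ungapped_length(aln)  # 3
#' @export
ungapped_length <- function(aln) {
  res <- as.integer(rowSums(aln$seq != "-" & aln$seq != "N"))
  names(res) <- aln$info$id
  res
}

#' Build an alignment from character strings (convenience constructor)
#'
#' @param x named character vector of equal-length sequences; names become
#'   ids and are parsed as headers via `scheme`.
#' @inheritParams read_fasta
#' @return A [barcode_alignment()].
#' @export
alignment_from_strings <- function(x, scheme = label_scheme(), frame = NA_integer_) {
  if (is.null(names(x))) names(x) <- sprintf("seq%03d", seq_along(x))
  lens <- nchar(x)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("ragged alignment: record '", names(x)[bad], "' has length ", lens[bad])
  }
  parsed <- lapply(names(x), parse_one_label, delim = scheme$delim,
                   id_field = scheme$id_field, species_field = scheme$species_field)
  info <- tibble(
    id = vapply(parsed, `[[`, character(1), "id"),
    label = names(x),
    species = vapply(parsed, `[[`, character(1), "species"),
    id_level = vapply(parsed, `[[`, character(1), "id_level")
  )
  m <- matrix(unlist(strsplit(toupper(x), ""), use.names = FALSE),
              nrow = length(x), byrow = TRUE)
  barcode_alignment(m, info, frame)
}

# Codon position of each alignment column given the codon position of
# column 1 (all coordinates 1-based).
codon_positions <- function(n_col, frame) {
  ((seq_len(n_col) - 1L + frame - 1L) %% 3L) + 1L
}

# Stop codons of the invertebrate mitochondrial translation table: TAA, TAG
# (TGA encodes Trp, AGA/AGG encode Ser in this code).
MITO_STOPS <- c("TAA", "TAG")

#' Detect the reading frame of a COI alignment
#'
#' Returns the codon position of alignment column 1 (1, 2 or 3) that
#' minimises the total number of in-frame stop codons under the
#' invertebrate mitochondrial code, across all records.  Codons containing
#' gaps or ambiguity codes are skipped.  Ties go to the smallest frame.
#' Functional COI should yield (near) zero stops in the true frame.
#'
#' @param aln a [barcode_alignment()].
#' @param set_frame if `TRUE` (default) return the alignment with `frame`
#'   set; if `FALSE` return the integer frame.
#' @return The alignment with frame set, or an integer in 1:3.
#' @export
detect_frame <- function(aln, set_frame = TRUE) {
  if (n_records(aln) == 0L) stop("empty alignment")
  counts <- vapply(1:3, function(f) count_stops(aln, f), numeric(1))
  frame <- which.min(counts)  # which.min takes the first = smallest on ties
  if (set_frame) {
    aln$frame <- as.integer(frame)
    aln
  } else {
    as.integer(frame)
  }
}

count_stops <- function(aln, frame) {
  pos <- codon_positions(ncol(aln$seq), frame)
  first <- which(pos == 1L)
  first <- first[first + 2L <= ncol(aln$seq)]
  if (length(first) == 0L) return(0)
  n <- 0
  for (s in first) {
    c1 <- aln$seq[, s]; c2 <- aln$seq[, s + 1L]; c3 <- aln$seq[, s + 2L]
    ok <- c1 %in% UNAMBIGUOUS & c2 %in% UNAMBIGUOUS & c3 %in% UNAMBIGUOUS
    cod <- paste0(c1[ok], c2[ok], c3[ok])
    n <- n + sum(cod %in% MITO_STOPS)
  }
  n
}
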