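# Compound library ingestion, validation and CID-level deduplication.
#
# A compound record is a row of a tibble with columns
#   cid     : positive integer PubChem identifier (unique within a library)
#   name    : free-text compound name
#   smiles  : SMILES string
#   sources : list-column, character set of origin labels
# Records lacking a usable CID are rejected with a logged reason rather than
# silently dropped; the rejection report travels alongside the records.

#' Column-name dialect for compound tables
#'
#' Maps the canonical column roles to the header names used by a particular
#' file. Defaults match the package's own serialization.
#'
#' @param cid,name,smiles,source Header names carrying each role.
#' @return Named list used by [parse_compound_table()].
#' @export
compound_dialect <- function(cid = "cid", name = "name",
                             smiles = "smiles", source = "source") {
  list(cid = cid, name = name, smiles = smiles, source = source)
}

#' Parse a compound table
#'
#' Reads a CSV/TSV compound table (delimiter auto-detected from the header
#' line) into validated compound records. Rows without a positive-integer CID
#' or without a SMILES string are rejected and reported, not kept.
#'
#' @param file Path to a CSV/TSV file, or literal text containing newlines.
#' @param dialect Column-name map from [compound_dialect()].
#' @return List with elements `compounds` (tibble: `cid`, `name`, `smiles`,
#'   `sources` list-column), `rejected` (tibble: `row`, `reason`) and
#'   `n_rejected`.
#' @export
parse_compound_table <- function(file, dialect = compound_dialect()) {
  input <- np_read_input(file)
  first <- if (inherits(input, "AsIs")) strsplit(input, "\n")[[1]][1] else readLines(input, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(input, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  for (role in c("cid", "smiles")) {
    if (!dialect[[role]] %in% names(tab)) {
      np_stop("np_format_error",
              "compound table is missing mandatory column '%s' (role: %s)",
              dialect[[role]], role)
    }
  }
  if (nrow(tab) == 0) {
    return(list(compounds = empty_compounds(), rejected = empty_rejects(),
                n_rejected = 0L))
  }
  cid_raw <- trimws(tab[[dialect$cid]])
  cid_num <- suppressWarnings(as.integer(cid_raw))
  smiles <- trimws(tab[[dialect$smiles]] %||% "")
  name <- if (dialect$name %in% names(tab)) tab[[dialect$name]] else NA_character_
  src <- if (dialect$source %in% names(tab)) tab[[dialect$source]] else "unknown"

  reason <- rep(NA_character_, nrow(tab))
  bad_cid <- is.na(cid_num) | cid_num <= 0 | !nzchar(cid_raw %||% "")
  reason[bad_cid] <- "missing or non-positive CID"
  bad_smiles <- !bad_cid & (is.na(smiles) | !nzchar(smiles))
  reason[bad_smiles] <- "missing SMILES"

  keep <- is.na(reason)
  compounds <- tibble(
    cid = cid_num[keep],
    name = as.character(name)[keep],
    smiles = smiles[keep],
    sources = lapply(strsplit(as.character(src)[keep], ";", fixed = TRUE),
                     function(s) unique(trimws(s)))
  )
  rejected <- tibble(row = which(!keep), reason = reason[!keep])
  list(compounds = compounds, rejected = rejected, n_rejected = nrow(rejected))
}

empty_compounds <- function() {
  tibble(cid = integer(), name = character(), smiles = character(),
         sources = list())
}
empty_rejects <- function() tibble(row = integer(), reason = character())

#' Serialize compound records
#'
#' Writes compound records back to CSV, joining each record's source set with
#' `";"` so that `parse_compound_table()` round-trips them exactly.
#'
#' @param compounds Tibble as returned by [parse_compound_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(compounds, path) {
  out <- tibble(
    cid = compounds$cid,
    name = compounds$name,
    smiles = compounds$smiles,
    source = vapply(compounds$sources, paste, character(1), collapse = ";")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Deduplicate compound records by PubChem CID
#'
#' One record is kept per CID: the first-seen record's name and SMILES win,
#' source sets of all duplicates are merged, and first-seen order is
#' preserved. Idempotent.
#'
#' @param compounds Tibble of compound records.
#' @return Tibble with one row per distinct CID.
#' @export
deduplicate_by_cid <- function(compounds) {
  if (nrow(compounds) == 0) return(compounds)
  idx <- split(seq_len(nrow(compounds)), factor(compounds$cid,
                                                levels = unique(compounds$cid)))
  first <- vapply(idx, `[[`, integer(1), 1L)
  out <- compounds[first, , drop = FALSE]
  out$sources <- lapply(idx, function(i) {
    unique(unlist(compounds$sources[i], use.names = FALSE))
  })
  out
}
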