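# Molecular descriptor computation behind a pluggable backend contract.
#
# Screening logic consumes a fixed descriptor vector:
#   mw (Da), tpsa (A^2), wlogp, mlogp, xlogp, hbd, hba, rotb, mr,
#   heavy_atoms, total_atoms, rings, carbons, heteroatoms
# Two backends ship: "openbabel" (computes descriptors from SMILES with the
# Open Babel command-line tool) and "table" (looks descriptors up in a
# precomputed table, the usual route for pipeline runs where descriptors come
# from an external engine snapshot).

descriptor_fields <- c("mw", "tpsa", "wlogp", "mlogp", "xlogp", "hbd", "hba",
                       "rotb", "mr", "heavy_atoms", "total_atoms", "rings",
                       "carbons", "heteroatoms")

new_descriptor_backend <- function(name, fn) {
  structure(list(name = name, fn = fn), class = "descriptor_backend")
}

#' @export
print.descriptor_backend <- function(x, ...) {
  cat("<descriptor_backend:", x$name, ">\n")
  invisible(x)
}

# Light syntactic SMILES validation: Open Babel silently repairs strings like
# "C(", so unbalanced brackets and dangling bonds are caught here instead.
smiles_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  if (!grepl("^[][A-Za-z0-9@+()=#$:/\\.%*-]+$", s)) return(FALSE)
  depth_p <- cumsum((chars == "(") - (chars == ")"))
  depth_b <- cumsum((chars == "[") - (chars == "]"))
  if (any(depth_p < 0) || any(depth_b < 0)) return(FALSE)
  if (depth_p[length(chars)] != 0 || depth_b[length(chars)] != 0) return(FALSE)
  if (grepl("[=#(/\\\\.\\-]$", s)) return(FALSE)
  ring_digits <- gsub("\\[[^]]*\\]", "", s)       # ignore digits inside []
  ring_digits <- gsub("%[0-9]{2}", "R", ring_digits)
  digs <- strsplit(gsub("[^0-9]", "", ring_digits), "")[[1]]
  all(table(digs) %% 2 == 0)
}

#' Open Babel descriptor backend
#'
#' Computes the full descriptor vector from SMILES with the `obabel`
#' command-line tool. Open Babel's Wildman-Crippen logP estimate fills the
#' `wlogp` slot and, lacking dedicated MLOGP/XLOGP3 models, is reused for
#' `mlogp` and `xlogp`; supply a precomputed table backend when
#' method-specific lipophilicity estimates matter.
#'
#' @param obabel Path to the `obabel` executable.
#' @return A `descriptor_backend` object.
#' @export
descriptor_backend_openbabel <- function(obabel = "obabel") {
  if (Sys.which(obabel) == "" && !file.exists(obabel)) {
    np_stop("np_config_error", "obabel executable not found ('%s')", obabel)
  }
  new_descriptor_backend("openbabel", function(smiles) {
    bad <- !vapply(smiles, smiles_syntax_ok, logical(1))
    if (any(bad)) {
      np_stop("np_parse_error", "unparseable SMILES: %s",
              paste(sQuote(smiles[bad]), collapse = ", "))
    }
    smi <- tempfile(fileext = ".smi")
    out <- tempfile(fileext = ".smi")
    on.exit(unlink(c(smi, out)), add = TRUE)
    ids <- sprintf("m%06d", seq_along(smiles))
    writeLines(paste(smiles, ids), smi)
    status <- suppressWarnings(system2(
      obabel, c(smi, "-osmi", "--append",
                shQuote("MW logP TPSA HBD HBA1 MR rotors atoms bonds formula"),
                "-O", out),
      stdout = FALSE, stderr = FALSE))
    lines <- if (file.exists(out)) readLines(out) else character()
    if (status != 0 || length(lines) != length(smiles)) {
      np_stop("np_parse_error",
              "Open Babel failed to convert %d of %d SMILES",
              length(smiles) - length(lines), length(smiles))
    }
    parts <- strsplit(sub("^[^\t]*\t", "", lines), " +")
    got_ids <- vapply(parts, `[[`, character(1), 1L)
    parts <- parts[match(ids, got_ids)]
    num <- function(i) vapply(parts, function(p) as.numeric(p[i + 1]), numeric(1))
    formula <- vapply(parts, function(p) p[11], character(1))
    counts <- lapply(formula, parse_formula)
    n_el <- function(el) vapply(counts, function(cc) {
      v <- unname(cc[el])
      if (length(v) == 0 || is.na(v)) 0 else v
    }, numeric(1))
    total <- vapply(counts, sum, numeric(1))
    heavy <- num(8)
    frags <- 1L + vapply(gsub("\\[[^]]*\\]", "", smiles),
                         function(s) sum(strsplit(s, "")[[1]] == "."), integer(1))
    d <- tibble(
      mw = num(1), tpsa = num(3), wlogp = num(2), mlogp = num(2),
      xlogp = num(2), hbd = num(4), hba = num(5), rotb = num(7),
      mr = num(6), heavy_atoms = heavy, total_atoms = total,
      rings = pmax(0, num(9) - heavy + frags),
      carbons = n_el("C"), heteroatoms = heavy - n_el("C")
    )
    d
  })
}

parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

#' Precomputed-table descriptor backend
#'
#' Serves descriptor vectors from a precomputed table (for example a CSV
#' exported from an external ADME engine), keyed by SMILES or by CID.
#'
#' @param table Data frame holding the key column plus all descriptor fields.
#' @param key Name of the key column (`"smiles"` or `"cid"`).
#' @return A `descriptor_backend` object.
#' @export
descriptor_backend_table <- function(table, key = "smiles") {
  table <- as_tibble(table)
  missing_cols <- setdiff(c(key, descriptor_fields), names(table))
  if (length(missing_cols) > 0) {
    np_stop("np_format_error", "descriptor table is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  new_descriptor_backend("table", function(keys) {
    i <- match(keys, table[[key]])
    if (anyNA(i)) {
      np_stop("np_parse_error", "no precomputed descriptors for: %s",
              paste(sQuote(keys[is.na(i)]), collapse = ", "))
    }
    table[i, descriptor_fields]
  })
}

#' Compute molecular descriptors
#'
#' @param smiles Character vector of SMILES strings (or table-backend keys).
#' @param backend A `descriptor_backend`, e.g. [descriptor_backend_openbabel()].
#' @return Tibble with one row per input and all 14 descriptor columns.
#' @export
compute_descriptors <- function(smiles, backend) {
  if (!inherits(backend, "descriptor_backend")) {
    np_stop("np_config_error", "backend must be a descriptor_backend object")
  }
  if (length(smiles) == 0) {
    np_stop("np_value_error", "no SMILES supplied")
  }
  d <- backend$fn(smiles)
  stopifnot(identical(names(d), descriptor_fields), nrow(d) == length(smiles))
  d
}

#' Attach precomputed descriptors to compound records
#'
#' Joins a CID-keyed descriptor table onto deduplicated compound records.
#'
#' @param compounds Tibble of compound records (column `cid`).
#' @param descriptors Data frame with `cid` plus all descriptor fields.
#' @return `compounds` with descriptor columns appended.
#' @export
attach_descriptors <- function(compounds, descriptors) {
  descriptors <- as_tibble(descriptors)
  missing_cols <- setdiff(c("cid", descriptor_fields), names(descriptors))
  if (length(missing_cols) > 0) {
    np_stop("np_format_error", "descriptor table is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  i <- match(compounds$cid, descriptors$cid)
  if (anyNA(i)) {
    np_stop("np_data_error", "no descriptors for CID(s): %s",
            paste(compounds$cid[is.na(i)], collapse = ", "))
  }
  dplyr::bind_cols(compounds, descriptors[i, descriptor_fields])
}
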