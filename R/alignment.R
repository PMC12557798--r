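#' Read an aligned amino-acid FASTA into an ortholog set
#'
#' Reads one aligned protein sequence per species. Sequences are
#' uppercase-normalized; ragged alignments and duplicate species identifiers
#' are rejected. In strict mode the alignment length must be 331 or 332
#' columns, the length window of the LDH-A ortholog family this package
#' targets.
#'
#' @param path Path to an aligned FASTA file.
#' @param strict_length If `TRUE`, require an alignment length of 331 or 332.
#' @return An object of class `ortholog_set`: a list with `species_ids`,
#'   `sequences` (named character vector of aligned residues over the 20
#'   amino acids plus `-`), and `alignment_length`.
#' @export
read_aligned_fasta <- function(path, strict_length = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ortholog_set(as.character(aa), names(aa), strict_length = strict_length)
}

#' Construct an aligned ortholog set
#'
#' @param sequences Character vector of aligned sequences (may be named by
#'   species).
#' @param species_ids Species identifiers, one per sequence.
#' @param strict_length Enforce the 331/332-column QC window.
#' @return An `ortholog_set` (see [read_aligned_fasta]).
#' @export
ortholog_set <- function(sequences, species_ids = names(sequences),
                         strict_length = FALSE) {
  force(species_ids)
  sequences <- toupper(as.character(sequences))
  if (is.null(species_ids)) stop("species identifiers are required")
  species_ids <- as.character(species_ids)
  if (length(species_ids) != length(sequences)) {
    stop("one species id per sequence required")
  }
  if (anyDuplicated(species_ids)) {
    stop("duplicate species ids: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  len <- lens[1]
  if (strict_length && !len %in% c(331L, 332L)) {
    stop("alignment length ", len, " outside the QC window {331, 332}")
  }
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY-]*$", sequences)
  if (!all(ok)) stop("non-standard residue codes in sequences: ",
                     paste(species_ids[!ok], collapse = ", "))
  names(sequences) <- species_ids
  structure(list(species_ids = species_ids, sequences = sequences,
                 alignment_length = as.integer(len)),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat("Aligned ortholog set:", length(x$species_ids), "species x",
      x$alignment_length, "columns\n")
  invisible(x)
}

#' Write an ortholog set to aligned FASTA
#'
#' @param x An `ortholog_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(x, path) {
  stopifnot(inherits(x, "ortholog_set"))
  writeLines(paste0(">", x$species_ids, "\n", unname(x$sequences)), path)
  invisible(path)
}

# alignment as a species x column character matrix
alignment_matrix <- function(x) {
  stopifnot(inherits(x, "ortholog_set"))
  m <- do.call(rbind, strsplit(unname(x$sequences), "", fixed = TRUE))
  rownames(m) <- x$species_ids
  m
}

#' Tritiered quality filter for coding sequences
#'
#' Applies the CDS quality-control rules used to admit ortholog coding
#' sequences: (a) the translation must end in a stop codon, (b) no internal
#' stop codon or unknown residue (X) may occur, and (c) the translated
#' protein must be at least `min_pident` percent identical to the reference
#' protein. A CDS whose length is not a multiple of three is rejected
#' outright.
#'
#' @param cds Named character vector of nucleotide coding sequences.
#' @param reference Reference protein sequence (single string) for the
#'   identity filter, or `NULL` to skip rule (c).
#' @param min_pident Minimum percentage of identical matches (default 90).
#' @return A list with `passed` (named character vector of translated
#'   proteins, terminal stop removed) and `rejected` (data.frame with `id`
#'   and `reason`).
#' @export
qc_filter_cds <- function(cds, reference = NULL, min_pident = 90) {
  if (is.null(names(cds))) names(cds) <- paste0("cds", seq_along(cds))
  passed <- character(0)
  rej_id <- character(0)
  rej_why <- character(0)
  reject <- function(id, why) {
    rej_id <<- c(rej_id, id)
    rej_why <<- c(rej_why, why)
  }
  for (id in names(cds)) {
    s <- toupper(cds[[id]])
    if (nchar(s) %% 3 != 0) {
      reject(id, "length not a multiple of 3")
      next
    }
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "X"))
    if (!endsWith(prot, "*")) {
      reject(id, "no terminal stop codon")
      next
    }
    body <- substr(prot, 1L, nchar(prot) - 1L)
    if (grepl("[*X]", body)) {
      reject(id, "internal stop or unknown residue")
      next
    }
    if (!is.null(reference)) {
      pid <- protein_pident(body, reference)
      if (is.na(pid) || pid < min_pident) {
        reject(id, sprintf("pident %.1f < %g", pid, min_pident))
        next
      }
    }
    passed[id] <- body
  }
  list(passed = passed,
       rejected = data.frame(id = rej_id, reason = rej_why,
                             stringsAsFactors = FALSE))
}

# percent identical matches over a global alignment of two proteins
protein_pident <- function(query, reference) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = "BLOSUM62", type = "global")
  Biostrings::pid(al, type = "PID1")
}

#' Tabulate substitution sites in an aligned ortholog set
#'
#' A substitution site is an alignment column where at least two distinct
#' non-gap residues occur. A gap is not treated as a variant: columns whose
#' only variation is gap-versus-residue are excluded from the substitution
#' list and reported separately, and species with a gap at a column are
#' excluded from that column's counts.
#'
#' @param x An `ortholog_set`.
#' @return An object of class `substitution_sites`: a list with
#'   * `sites`: list of per-site records (`position` 1-based column,
#'     `counts` named residue counts, `gap_count`),
#'   * `site_residues`: species x site character matrix of residues at the
#'     substitution sites (gaps as `-`),
#'   * `gap_columns`: integer vector of columns containing any gap,
#'   * `n_species`, `species_ids`.
#' @export
find_substitution_sites <- function(x) {
  m <- alignment_matrix(x)
  n <- nrow(m)
  is_sub <- logical(ncol(m))
  gap_cols <- integer(0)
  sites <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gaps <- col == "-"
    if (any(gaps)) gap_cols <- c(gap_cols, j)
    tab <- table(col[!gaps])
    if (length(tab) >= 2L) {
      is_sub[j] <- TRUE
      cnt <- as.integer(tab)
      names(cnt) <- names(tab)
      sites[[length(sites) + 1L]] <- list(position = j, counts = cnt,
                                          gap_count = sum(gaps))
    }
  }
  pos <- vapply(sites, `[[`, integer(1), "position")
  sr <- m[, pos, drop = FALSE]
  colnames(sr) <- as.character(pos)
  structure(list(sites = sites, site_residues = sr,
                 gap_columns = gap_cols, n_species = n,
                 species_ids = rownames(m)),
            class = "substitution_sites")
}

#' @export
print.substitution_sites <- function(x, ...) {
  cat("Substitution sites:", length(x$sites), "polymorphic columns among",
      x$n_species, "species;", length(x$gap_columns),
      "columns contain gaps\n")
  invisible(x)
}

#' Export substitution sites as a long table
#'
#' @param x A `substitution_sites` object.
#' @return data.frame with one row per site x residue: `site`, `residue`,
#'   `count`, `gap_count`.
#' @export
substitution_site_table <- function(x) {
  stopifnot(inherits(x, "substitution_sites"))
  rows <- lapply(x$sites, function(s) {
    data.frame(site = s$position, residue = names(s$counts),
               count = unname(s$counts), gap_count = s$gap_count,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(site = integer(0), residue = character(0),
                      count = integer(0), gap_count = integer(0)))
  }
  do.call(rbind, rows)
}
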