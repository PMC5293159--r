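#' Column dialect for wide SILAC quantification tables
#'
#' Fraction-wise PCP-SILAC quantification arrives as a wide table with one
#' ratio column per isotopologue channel and fraction (MaxQuant style,
#' e.g. `"Ratio M/L 12"`). A dialect names the identifier column, the
#' regular expression that recognises ratio columns (first capture group =
#' channel, second = fraction index), the flag columns for reverse-database
#' and contaminant hits, and an optional mapping from channel letters to
#' experimental conditions.
#'
#' @param id_col Name of the protein-group accession column.
#' @param ratio_pattern Regex with two capture groups (channel, fraction).
#' @param reverse_col,contaminant_col Flag columns; rows marked `"+"` are
#'   removed.
#' @param channel_map Optional named character vector renaming channels,
#'   e.g. `c(M = "untreated", H = "treated")`.
#' @param peptide_cols Optional named list with `sequence`, `start`, `end`
#'   column names for peptide-level tables.
#' @return A list of class `quant_dialect`.
#' @export
quant_dialect <- function(id_col = "Protein IDs",
                          ratio_pattern = "^Ratio ([MH])/L (\\d+)$",
                          reverse_col = "Reverse",
                          contaminant_col = "Potential contaminant",
                          channel_map = c(M = "untreated", H = "treated"),
                          peptide_cols = NULL) {
  structure(
    list(id_col = id_col, ratio_pattern = ratio_pattern,
         reverse_col = reverse_col, contaminant_col = contaminant_col,
         channel_map = channel_map, peptide_cols = peptide_cols),
    class = "quant_dialect"
  )
}

#' Read a fraction-wise SILAC quantification table
#'
#' Reads a wide MaxQuant-style protein-group (or peptide) table, removes
#' rows flagged as reverse-database matches or common contaminants, checks
#' that the fraction columns form a contiguous `1..F` axis, and returns the
#' quantification in long (tidy) form: one row per accession, channel and
#' fraction. Missing measurements (empty cells or `NaN`) become `NA`.
#'
#' @param path Path to a tab-separated file.
#' @param dialect A [quant_dialect()] describing the column layout.
#' @param normalize_fractions If `TRUE`, each channel-fraction column is
#'   divided by its median across proteins before analysis. Off by default;
#'   PCP ratios are already expressed relative to a spiked reference.
#' @return A tibble with columns `protein`, `channel`, `fraction`, `ratio`
#'   (plus `peptide`, `start`, `end` for peptide tables), carrying
#'   attributes `n_fractions` and `n_removed`.
#' @export
read_quant_table <- function(path, dialect = quant_dialect(),
                             normalize_fractions = FALSE) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA", "NaN"), progress = FALSE)
  if (!dialect$id_col %in% names(raw)) {
    stop_cofrac(sprintf("missing mandatory column '%s'", dialect$id_col),
                "cofrac_format_error")
  }

  hits <- str_match(names(raw), dialect$ratio_pattern)
  ratio_cols <- which(!is.na(hits[, 1]))
  if (length(ratio_cols) == 0) {
    stop_cofrac(sprintf("no columns match the ratio pattern '%s'",
                        dialect$ratio_pattern), "cofrac_format_error")
  }
  fractions <- as.integer(hits[ratio_cols, 3])
  f_range <- sort(unique(fractions))
  n_f <- max(f_range)
  if (!identical(f_range, seq_len(n_f))) {
    stop_cofrac(sprintf(
      "fraction columns must form a contiguous 1..F range; found {%s}",
      paste(f_range, collapse = ",")), "cofrac_format_error")
  }

  n0 <- nrow(raw)
  flagged <- rep(FALSE, n0)
  for (fc in c(dialect$reverse_col, dialect$contaminant_col)) {
    if (!is.null(fc) && fc %in% names(raw)) {
      flagged <- flagged | (!is.na(raw[[fc]]) & raw[[fc]] != "")
    }
  }
  raw <- raw[!flagged, , drop = FALSE]
  inform(sprintf("read_quant_table: removed %d flagged row(s), retained %d",
                 sum(flagged), nrow(raw)))
  if (nrow(raw) == 0) {
    stop_cofrac("no data rows remain after reverse/contaminant filtering",
                "cofrac_empty_input_error")
  }

  keep <- tibble(protein = raw[[dialect$id_col]])
  pc <- dialect$peptide_cols
  if (!is.null(pc)) {
    for (nm in c("sequence", "start", "end")) {
      if (!is.null(pc[[nm]]) && !pc[[nm]] %in% names(raw)) {
        stop_cofrac(sprintf("missing mandatory column '%s'", pc[[nm]]),
                    "cofrac_format_error")
      }
    }
    keep$peptide <- raw[[pc$sequence]]
    keep$start <- as.integer(raw[[pc$start]])
    keep$end <- as.integer(raw[[pc$end]])
  }

  long <- purrr::map(ratio_cols, function(j) {
    out <- keep
    out$channel <- hits[j, 2]
    out$fraction <- as.integer(hits[j, 3])
    out$ratio <- suppressWarnings(as.numeric(raw[[j]]))
    out
  }) |> list_rbind()
  if (any(long$ratio < 0, na.rm = TRUE)) {
    stop_cofrac("negative ratio values are not valid SILAC ratios",
                "cofrac_format_error")
  }
  if (!is.null(dialect$channel_map)) {
    mapped <- unname(dialect$channel_map[long$channel])
    long$channel <- ifelse(is.na(mapped), long$channel, mapped)
  }
  if (normalize_fractions) {
    long <- long |>
      group_by(.data$channel, .data$fraction) |>
      mutate(ratio = .data$ratio / median(.data$ratio, na.rm = TRUE)) |>
      ungroup()
  }
  long <- arrange(long, .data$protein, .data$channel, .data$fraction)
  attr(long, "n_fractions") <- n_f
  attr(long, "n_removed") <- sum(flagged)
  long
}

#' Read a gold-standard complex database
#'
#' Parses a CORUM-like headerless TSV with three columns: complex id,
#' complex name, and semicolon-separated member accessions. Duplicate
#' members within a complex are removed with a warning; complexes with
#' fewer than two distinct members are dropped (with a warning), since they
#' define no interaction.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `complex_id`, `complex_name`, `members`
#'   (list column of character vectors) and `n_members`.
#' @export
read_complex_db <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_names = c("complex_id", "complex_name", "members"),
                         col_types = "ccc", progress = FALSE)
  db <- raw |>
    mutate(members = str_split(.data$members, ";")) |>
    mutate(members = map(.data$members, ~ .x[.x != ""]))
  n_dup <- sum(map_int(db$members, ~ length(.x) - length(unique(.x))))
  if (n_dup > 0) {
    warn(sprintf("removed %d duplicate member(s) within complexes", n_dup))
    db$members <- map(db$members, unique)
  }
  db$n_members <- map_int(db$members, length)
  small <- db$n_members < 2
  if (any(small)) {
    warn(sprintf("dropped %d complex(es) with fewer than 2 members", sum(small)))
    db <- db[!small, , drop = FALSE]
  }
  if (nrow(db) == 0) {
    stop_cofrac("no complexes with >= 2 members in database",
                "cofrac_empty_input_error")
  }
  db
}

#' Read cellular-component GO annotations from a GAF-like file
#'
#' Uses columns 2 (accession), 5 (GO id) and 9 (aspect) of the GAF 2.x
#' layout; only cellular-component (`C`) annotations are retained.
#' Membership of the membrane compartment is decided by matching against a
#' supplied list of membrane GO term ids (no ontology traversal).
#'
#' @param path Path to the GAF file (lines starting with `!` are comments).
#' @param membrane_terms Character vector of GO ids considered
#'   membrane-related.
#' @return Tibble with `accession`, `go_id`, `aspect`, `is_membrane`.
#' @export
read_go_annotations <- function(path, membrane_terms = character()) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(raw) < 9) {
    stop_cofrac("GAF file must have at least 9 tab-separated columns",
                "cofrac_format_error")
  }
  ann <- tibble(accession = raw[[2]], go_id = raw[[5]], aspect = raw[[9]])
  bad <- !str_detect(ann$go_id, "^GO:\\d{7}$")
  if (any(bad)) {
    stop_cofrac(sprintf("%d syntactically invalid GO id(s), e.g. '%s'",
                        sum(bad), ann$go_id[which(bad)[1]]),
                "cofrac_format_error")
  }
  ann <- filter(ann, .data$aspect == "C")
  ann$is_membrane <- ann$go_id %in% membrane_terms
  ann
}

#' Write and re-read an interaction network as TSV
#'
#' Edges are written in canonical order (`protein_a < protein_b`
#' lexicographically) with their score, gold-standard label, the
#' replicate/channel detections supporting them, and the condition call.
#' Writing an empty edge set produces a header-only file with a warning.
#'
#' @param edges Tibble with at least `protein_a`, `protein_b`; optional
#'   `score`, `label`, `support` (list of `"replicate:channel"` strings or
#'   pre-joined string) and `condition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  if (nrow(edges) == 0) {
    warn("writing an empty network (header only)")
    out <- tibble(protein_a = character(), protein_b = character(),
                  score = numeric(), label = character(),
                  support = character(), condition = character())
    readr::write_tsv(out, path)
    return(invisible(path))
  }
  cp <- canonical_pair(edges$protein_a, edges$protein_b)
  out <- tibble(
    protein_a = cp$protein_a,
    protein_b = cp$protein_b,
    score = edges$score %||% NA_real_,
    label = edges$label %||% NA_character_,
    support = if (is.list(edges$support %||% NULL)) {
      map_chr(edges$support, paste, collapse = ";")
    } else {
      edges$support %||% NA_character_
    },
    condition = edges$condition %||% NA_character_
  ) |>
    arrange(.data$protein_a, .data$protein_b)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  readr::read_tsv(path, col_types = "ccdccc", progress = FALSE)
}

#' Write complex clusters as TSV
#'
#' One row per cluster: id, elution centre (reported to 0.1 fraction) and
#' semicolon-separated members.
#'
#' @param clusters Tibble with `cluster_id`, `center` and `members` (list
#'   column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  if (nrow(clusters) == 0) {
    warn("writing an empty cluster table (header only)")
  }
  out <- tibble(
    cluster_id = clusters$cluster_id %||% character(),
    center_fraction = round(clusters$center %||% numeric(), 1),
    members = map_chr(clusters$members %||% list(), paste, collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read or write a protein FASTA file
#'
#' Thin wrappers over Biostrings returning/accepting a plain named
#' character vector of amino-acid sequences (names truncated at the first
#' whitespace).
#'
#' @param path FASTA path.
#' @return `read_proteome_fasta()`: named character vector.
#' @export
read_proteome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_cofrac("the Biostrings package is required to read FASTA files",
                "cofrac_dependency_error")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' @rdname read_proteome_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_proteome_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_cofrac("the Biostrings package is required to write FASTA files",
                "cofrac_dependency_error")
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
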