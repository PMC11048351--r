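# Readers and writers for the external representations the pipeline consumes:
# per-compartment abundance tables, miRNA FASTA, CISBP-RNA-style motif files,
# and the result tables the downstream stages emit.

VALID_COMPARTMENTS <- c("CELL", "SEV")
RNA_BASES <- c("A", "C", "G", "U")

#' Construct an abundance profile
#'
#' An abundance profile holds, for one compartment (intracellular or small
#' extracellular vesicle), a matrix of linear-scale signal intensities and the
#' matching detected-above-background (DABG) p-values, one column per
#' biological replicate.
#'
#' @param compartment Either `"CELL"` or `"SEV"`.
#' @param mirna_ids Character vector of miRNA identifiers (unique).
#' @param signals Numeric matrix, miRNA by replicate, non-negative.
#' @param detection_p Numeric matrix of DABG p-values in \[0, 1\], same shape
#'   as `signals`.
#' @return An object of class `abundance_profile`.
#' @export
abundance_profile <- function(compartment, mirna_ids, signals, detection_p) {
  compartment <- match.arg(toupper(compartment), VALID_COMPARTMENTS)
  signals <- as.matrix(signals)
  detection_p <- as.matrix(detection_p)
  if (anyDuplicated(mirna_ids))
    stop("duplicate miRNA identifiers: ",
         paste(unique(mirna_ids[duplicated(mirna_ids)]), collapse = ", "))
  if (length(mirna_ids) != nrow(signals))
    stop("mirna_ids length does not match signal rows")
  if (!identical(dim(signals), dim(detection_p)))
    stop("signals and detection_p must have identical dimensions")
  if (ncol(signals) < 2L)
    stop("at least 2 replicates are required, got ", ncol(signals))
  bad <- which(!is.finite(signals) | signals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-finite signal for miRNA '%s', replicate %d",
                 mirna_ids[bad[1, 1]], bad[1, 2]))
  bad <- which(!is.finite(detection_p) | detection_p < 0 | detection_p > 1,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("detection p outside [0,1] for miRNA '%s', replicate %d",
                 mirna_ids[bad[1, 1]], bad[1, 2]))
  dimnames(signals) <- dimnames(detection_p) <- list(mirna_ids, NULL)
  structure(list(compartment = compartment,
                 mirna_ids = as.character(mirna_ids),
                 signals = signals,
                 detection_p = detection_p),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("abundance_profile [%s]: %d miRNAs x %d replicates\n",
              x$compartment, length(x$mirna_ids), ncol(x$signals)))
  invisible(x)
}

#' Read a per-compartment abundance table
#'
#' Expects a tab-separated file with a header row and columns `mirna_id`,
#' then paired `signal_rep<i>` / `dabg_p_rep<i>` columns, one pair per
#' replicate. Row order is preserved.
#'
#' @param path Path to the TSV file.
#' @param compartment `"CELL"` or `"SEV"`.
#' @return An [abundance_profile()].
#' @export
read_abundance_table <- function(path, compartment) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"mirna_id" %in% names(df))
    stop("abundance table ", path, " is missing the 'mirna_id' column")
  sig_cols <- grep("^signal_rep[0-9]+$", names(df), value = TRUE)
  p_cols <- grep("^dabg_p_rep[0-9]+$", names(df), value = TRUE)
  if (length(sig_cols) == 0)
    stop("abundance table ", path, " has no signal_rep<i> columns")
  reps <- sort(as.integer(sub("^signal_rep", "", sig_cols)))
  want_sig <- paste0("signal_rep", reps)
  want_p <- paste0("dabg_p_rep", reps)
  missing <- setdiff(c(want_sig, want_p), names(df))
  if (length(missing) > 0)
    stop("abundance table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  abundance_profile(compartment,
                    df$mirna_id,
                    as.matrix(df[, want_sig, drop = FALSE]),
                    as.matrix(df[, want_p, drop = FALSE]))
}

#' Write an abundance profile as a TSV table
#'
#' Inverse of [read_abundance_table()]: `read(write(x))` reproduces `x`.
#'
#' @param profile An [abundance_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(profile, path) {
  stopifnot(inherits(profile, "abundance_profile"))
  n_rep <- ncol(profile$signals)
  out <- data.frame(mirna_id = profile$mirna_ids, stringsAsFactors = FALSE)
  for (i in seq_len(n_rep)) {
    out[[paste0("signal_rep", i)]] <- profile$signals[, i]
    out[[paste0("dabg_p_rep", i)]] <- profile$detection_p[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated RNA sequence set
#'
#' @param records Named character vector of sequences; names are miRNA ids.
#'   `T` is mapped to `U` and lowercase letters are uppercased.
#' @return Named character vector of class `sequence_set`.
#' @export
sequence_set <- function(records) {
  if (length(records) == 0)
    return(structure(stats::setNames(character(0), character(0)),
                     class = "sequence_set"))
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("every sequence must be named by a miRNA id")
  if (anyDuplicated(names(records)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(records)[duplicated(names(records))]),
               collapse = ", "))
  seqs <- chartr("Tt", "Uu", as.character(records))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", names(records)[!nzchar(seqs)][1], "'")
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("non-ACGT/U character in record '", names(records)[bad][1], "'")
  names(seqs) <- names(records)
  structure(seqs, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  if (length(x) == 0) cat("sequence_set: 0 RNA sequences\n")
  else cat(sprintf("sequence_set: %d RNA sequences (lengths %d-%d)\n",
                   length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Read miRNA sequences from FASTA
#'
#' DNA or RNA alphabet is accepted; sequences are normalized to uppercase
#' ACGU. Duplicate record ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))  # keep the id token of the header
  sequence_set(stats::setNames(as.character(ss), ids))
}

#' Write a sequence set as FASTA
#'
#' @param seqs A [sequence_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "sequence_set"))
  ss <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Normalize a position frequency matrix
#'
#' Divides each row (motif position) by its sum. Idempotent. Rows that sum to
#' zero are an error.
#'
#' @param pfm Numeric matrix, width x 4, columns in A, C, G, U order.
#' @return Row-normalized matrix with columns named A, C, G, U.
#' @export
normalize_pfm <- function(pfm) {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4) stop("PFM must have 4 columns (A, C, G, U)")
  rs <- rowSums(pfm)
  if (any(!is.finite(rs) | rs <= 0))
    stop("PFM row ", which(!is.finite(rs) | rs <= 0)[1],
         " has zero or invalid sum")
  out <- pfm / rs
  colnames(out) <- RNA_BASES
  out
}

#' Most-probable-base consensus of a PFM
#'
#' Ties are broken alphabetically (A < C < G < U).
#'
#' @param pfm Width x 4 frequency matrix.
#' @return Consensus string.
#' @export
pfm_consensus <- function(pfm) {
  pfm <- normalize_pfm(pfm)
  paste(RNA_BASES[apply(pfm, 1, which.max)], collapse = "")
}

#' Construct a motif model
#'
#' @param motif_id Motif identifier.
#' @param pfm Width x 4 position frequency matrix (rows renormalized).
#' @param rbp_name Name of the RNA-binding protein the motif belongs to.
#' @param species Species the motif was determined in.
#' @return An object of class `motif_model` with fields `motif_id`,
#'   `rbp_name`, `species`, `pfm` and `consensus`.
#' @export
motif_model <- function(motif_id, pfm, rbp_name = motif_id,
                        species = "unknown") {
  pfm <- normalize_pfm(pfm)
  if (nrow(pfm) < 3) stop("motif '", motif_id, "' is shorter than 3 positions")
  structure(list(motif_id = as.character(motif_id),
                 rbp_name = as.character(rbp_name),
                 species = as.character(species),
                 pfm = pfm,
                 consensus = pfm_consensus(pfm)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s (%s, %s): width %d, consensus %s\n",
              x$motif_id, x$rbp_name, x$species, nrow(x$pfm), x$consensus))
  invisible(x)
}

#' Build a near-deterministic motif from a consensus string
#'
#' Each position puts all frequency mass on the consensus base, matching the
#' way fixture motifs are specified from printed consensus strings.
#'
#' @param consensus Consensus string over A, C, G, U (T accepted, mapped to U).
#' @inheritParams motif_model
#' @return A [motif_model()].
#' @export
motif_from_consensus <- function(consensus, motif_id = consensus,
                                 rbp_name = motif_id, species = "synthetic") {
  bases <- strsplit(toupper(chartr("T", "U", consensus)), "")[[1]]
  if (any(!bases %in% RNA_BASES))
    stop("consensus contains non-ACGU characters: ", consensus)
  pfm <- matrix(0, nrow = length(bases), ncol = 4,
                dimnames = list(NULL, RNA_BASES))
  pfm[cbind(seq_along(bases), match(bases, RNA_BASES))] <- 1
  motif_model(motif_id, pfm, rbp_name, species)
}

#' Read CISBP-RNA-style motif files
#'
#' Each motif lives in its own whitespace-separated text file with a header
#' row `Pos A C G U` (a `T` column header is accepted and mapped to `U`) and
#' one row per motif position. A metadata TSV maps `Motif_ID` to the RBP name
#' and species; motifs absent from the metadata are skipped with a warning.
#'
#' @param pwm_dir Directory containing one `.txt` file per motif; the file
#'   name (without extension) is the motif id.
#' @param metadata Path to a TSV with columns `Motif_ID`, `RBP_Name`,
#'   `RBP_Species`.
#' @return List of [motif_model()] objects.
#' @export
read_cisbp_motifs <- function(pwm_dir, metadata) {
  meta <- utils::read.table(metadata, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("Motif_ID", "RBP_Name", "RBP_Species")
  if (!all(need %in% names(meta)))
    stop("motif metadata must have columns: ", paste(need, collapse = ", "))
  files <- list.files(pwm_dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop("no .txt motif files found in ", pwm_dir)
  out <- list()
  for (f in sort(files)) {
    id <- sub("\\.txt$", "", basename(f))
    pfm <- read_cisbp_pwm_file(f)
    row <- match(id, meta$Motif_ID)
    if (is.na(row)) {
      warning("motif '", id, "' has no metadata entry; skipped", call. = FALSE)
      next
    }
    out[[id]] <- motif_model(id, pfm,
                             rbp_name = meta$RBP_Name[row],
                             species = meta$RBP_Species[row])
  }
  out
}

# One CISBP PWM text file -> width x 4 frequency matrix (columns A,C,G,U).
read_cisbp_pwm_file <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab) <- toupper(names(tab))
  if ("T" %in% names(tab) && !"U" %in% names(tab))
    names(tab)[names(tab) == "T"] <- "U"
  if (!all(RNA_BASES %in% names(tab)))
    stop("motif file ", path, " lacks A/C/G/U (or T) frequency columns")
  normalize_pfm(as.matrix(tab[, RNA_BASES]))
}

#' Write a motif model as a CISBP-style text file
#'
#' @param motif A [motif_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cisbp_motif <- function(motif, path) {
  stopifnot(inherits(motif, "motif_model"))
  tab <- data.frame(Pos = seq_len(nrow(motif$pfm)), motif$pfm,
                    check.names = FALSE)
  utils::write.table(format(tab, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif metadata for a set of motif models
#'
#' @param motifs List of [motif_model()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_motif_metadata <- function(motifs, path) {
  tab <- data.frame(
    Motif_ID = vapply(motifs, `[[`, "", "motif_id"),
    RBP_Name = vapply(motifs, `[[`, "", "rbp_name"),
    RBP_Species = vapply(motifs, `[[`, "", "species"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter motifs to one species
#'
#' Mirrors a single-species CISBP-RNA query; motifs recorded from homologous
#' proteins in other species can be admitted explicitly.
#'
#' @param motifs List of [motif_model()] objects.
#' @param species Species to keep (exact match on the metadata field).
#' @param include_homologs If `TRUE`, motifs from any species are retained.
#' @return Filtered list.
#' @export
filter_motifs_by_species <- function(motifs, species = "Mus_musculus",
                                     include_homologs = FALSE) {
  if (include_homologs) return(motifs)
  keep <- vapply(motifs, function(m) identical(m$species, species), logical(1))
  motifs[keep]
}
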