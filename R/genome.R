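# GenomeSeq: a loaded genome with contig structure and cached base codes.

#' Construct a GenomeSeq from in-memory sequences
#'
#' Contigs are concatenated in the given order; coordinates are 0-based
#' half-open throughout.  Lowercase letters are uppercased; IUPAC ambiguity
#' letters other than `A/C/G/T` are recorded as `N` (which matches nothing
#' when counting); anything else is rejected.
#'
#' @param sequences Character vector, one element per contig.
#' @param name Genome name.
#' @param circular Logical, recycled to one flag per contig.
#' @param contig_names Optional contig names.
#' @return An object of class `GenomeSeq` with fields `name`, `residues`
#'   (concatenated string), `contig_bounds` (two-column matrix of 0-based
#'   half-open intervals), `circular`, `length` and `gc_fraction` (computed
#'   over `A/C/G/T` only).
#' @export
genome_seq <- function(sequences, name = "genome", circular = FALSE,
                       contig_names = NULL) {
  if (length(sequences) == 0L || all(nchar(sequences) == 0L)) {
    stop("no sequence: genome has no residues", call. = FALSE)
  }
  if (is.null(contig_names)) {
    contig_names <- names(sequences)
    if (is.null(contig_names)) {
      contig_names <- sprintf("contig_%d", seq_along(sequences))
    }
  }
  sequences <- toupper(sequences)
  codes_list <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    letters <- strsplit(sequences[i], "")[[1]]
    code <- match(letters, .BASES)
    amb <- is.na(code)
    if (any(amb)) {
      ok <- letters[amb] %in% .IUPAC_LETTERS
      if (!all(ok)) {
        off <- which(amb)[which(!ok)[1]]
        stop(sprintf(
          "parse error: illegal character '%s' at offset %d of record '%s'",
          letters[off], off, contig_names[i]), call. = FALSE)
      }
      code[amb] <- 5L
      letters[amb] <- "N"
      sequences[i] <- paste0(letters, collapse = "")
    }
    codes_list[[i]] <- code
  }
  lens <- nchar(sequences)
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  bounds <- cbind(start = starts, end = ends)
  rownames(bounds) <- contig_names
  codes <- unlist(codes_list, use.names = FALSE)
  acgt <- codes <= 4L
  gc <- sum(codes == 2L | codes == 3L) / sum(acgt)
  structure(list(
    name          = name,
    residues      = paste0(sequences, collapse = ""),
    codes         = codes,
    contig_bounds = bounds,
    circular      = rep_len(as.logical(circular), length(sequences)),
    length        = sum(lens),
    gc_fraction   = gc
  ), class = "GenomeSeq")
}

#' Load a genome from a FASTA file
#'
#' All records are concatenated in file order, each kept as a separate
#' contig; oligomer matches never span contig boundaries.
#'
#' @param path Path to a (multi-record, possibly line-wrapped) FASTA file.
#' @param circular Default circularity flag applied to every contig.
#' @param name Genome name; defaults to the file name without extension.
#' @return A [genome_seq()] object.
#' @export
load_fasta <- function(path, circular = FALSE, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    stop("no sequence: FASTA file '", path, "' contains no records",
         call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  genome_seq(as.character(recs), name = name, circular = circular,
             contig_names = sub("\\s.*$", "", names(recs)))
}

#' @export
print.GenomeSeq <- function(x, ...) {
  cat(sprintf("GenomeSeq '%s': %d nt in %d contig(s), GC %.4f\n",
              x$name, x$length, nrow(x$contig_bounds), x$gc_fraction))
  circ <- ifelse(x$circular, "circular", "linear")
  for (i in seq_len(nrow(x$contig_bounds))) {
    cat(sprintf("  %s [%d, %d) %s\n", rownames(x$contig_bounds)[i],
                x$contig_bounds[i, 1], x$contig_bounds[i, 2], circ[i]))
  }
  invisible(x)
}

# number of contigs
n_contigs <- function(genome) nrow(genome$contig_bounds)

# integer codes of contig i (1-based slice of the concatenated codes)
contig_codes <- function(genome, i) {
  b <- genome$contig_bounds
  genome$codes[(b[i, 1] + 1L):b[i, 2]]
}

# genome (or single contig) as character string
genome_string <- function(genome) genome$residues
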