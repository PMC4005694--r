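# Genetic code, synonymous-family partition, tRNA isoacceptor groups.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Genetic code table
#'
#' Returns the codon to amino-acid map for an NCBI translation table.
#' Tables 1 (standard) and 11 (bacterial/archaeal/plastid) are supported;
#' their codon assignments are identical, so the synonymous-family
#' partition does not depend on the choice.
#'
#' @param table_id NCBI translation table identifier, 1 or 11.
#' @return An object of class \code{genetic_code}: a list with
#'   \code{table_id} and \code{codon_to_aa}, a named character vector over
#'   all 64 DNA codons with stops encoded as \code{"*"}.
#' @examples
#' code <- standard_code(11)
#' code$codon_to_aa[["TCA"]]  # "S"
#' @export
standard_code <- function(table_id = 11) {
  if (!table_id %in% c(1L, 11L))
    stop("unsupported translation table: ", table_id, " (supported: 1, 11)")
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- stats::setNames(as.vector(map), names(map))
  stopifnot(length(map) == 64L)
  structure(list(table_id = as.integer(table_id), codon_to_aa = map),
            class = "genetic_code")
}

STOP_AA <- "*"

new_family <- function(name, amino_acid, codons) {
  structure(list(name = name, amino_acid = amino_acid,
                 codons = sort(codons), degeneracy = length(codons)),
            class = "synonymous_family")
}

#' @export
print.synonymous_family <- function(x, ...) {
  cat(sprintf("<%s> %s: %s\n", x$name, x$amino_acid,
              paste(x$codons, collapse = " ")))
  invisible(x)
}

#' Partition the genetic code into synonymous codon families
#'
#' Groups codons by amino acid and, by default, splits the three 6-fold
#' degenerate amino acids (Leu, Ser, Arg) into a 4-codon quartet sharing
#' the first two bases and a 2-codon doublet (Ser4 = TCN vs Ser2 = AGY,
#' Arg4 = CGN vs Arg2 = AGR, Leu4 = CTN vs Leu2 = TTR), following the
#' degeneracy rules under which these blocks are normally tabulated.
#' Met, Trp (degeneracy 1) and stop codons yield no family.
#'
#' @param code A \code{genetic_code} from \code{\link{standard_code}}.
#' @param split_sixfold Split 6-fold families into quartet + doublet
#'   (default \code{TRUE}); if \code{FALSE} each amino acid is one block.
#' @return Named list of \code{synonymous_family} objects (e.g.
#'   \code{Ser4}, \code{Ser2}, \code{Val4}, \code{Ile3}, \code{Phe2}).
#' @examples
#' fams <- partition_families(standard_code(11))
#' fams$Ser2$codons  # "AGC" "AGT"
#' @export
partition_families <- function(code = standard_code(11), split_sixfold = TRUE) {
  map <- code$codon_to_aa
  by_aa <- split(names(map), map)
  by_aa[[STOP_AA]] <- NULL
  fams <- list()
  for (aa in names(by_aa)) {
    codons <- by_aa[[aa]]
    if (length(codons) < 2L) next
    aa3 <- AA3[[aa]]
    if (split_sixfold && length(codons) == 6L) {
      # quartet = the 4 codons sharing their first two bases
      stem <- substr(codons, 1L, 2L)
      quartet <- codons[stem %in% names(which(table(stem) == 4L))]
      doublet <- setdiff(codons, quartet)
      fams[[paste0(aa3, 4L)]] <- new_family(paste0(aa3, 4L), aa, quartet)
      fams[[paste0(aa3, 2L)]] <- new_family(paste0(aa3, 2L), aa, doublet)
    } else {
      nm <- paste0(aa3, length(codons))
      fams[[nm]] <- new_family(nm, aa, codons)
    }
  }
  fams[order(names(fams))]
}

# -- wobble decoding ---------------------------------------------------------

revcomp_chr <- function(x) {
  chartr("ACGTRYKMBDHVN", "TGCAYRMKVHDBN",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

#' Codons decoded by an anticodon under wobble rules
#'
#' Codon positions 1-2 pair strictly (reverse complement of anticodon
#' positions 3-2). At the wobble (codon third / anticodon first) position:
#' anticodon G reads codon C or T, T reads A or G, C reads G only and
#' (unmodified) A reads T only. Base modifications that restrict or extend
#' wobble cannot be inferred from sequence, so shipped isoacceptor
#' configurations list decoded codons explicitly and this function is the
#' default used when a configuration is silent.
#'
#' @param anticodon 3-letter DNA anticodon, 5' to 3' (e.g. "GCT").
#' @return Character vector of decoded codons.
#' @examples
#' wobble_codons("GCT")  # AGC AGT
#' @export
wobble_codons <- function(anticodon) {
  anticodon <- toupper(anticodon)
  stopifnot(nchar(anticodon) == 3L)
  stem <- revcomp_chr(substr(anticodon, 2L, 3L))   # codon positions 1-2
  third <- switch(substr(anticodon, 1L, 1L),
                  G = c("C", "T"), T = c("A", "G"),
                  C = "G", A = "T",
                  stop("wobble base must be one of ACGT: ", anticodon))
  paste0(stem, third)
}

new_isoacceptor_map <- function(anticodon, amino_acid, copy_number, codons) {
  stopifnot(length(anticodon) == length(codons),
            length(anticodon) == length(copy_number))
  structure(list(anticodon = anticodon, amino_acid = amino_acid,
                 copy_number = as.integer(copy_number), codons = codons),
            class = "isoacceptor_map")
}

#' @export
print.isoacceptor_map <- function(x, ...) {
  cat(sprintf("<isoacceptor_map> %d anticodons\n", length(x$anticodon)))
  for (i in seq_along(x$anticodon))
    cat(sprintf("  %s-%s (x%d): %s\n", x$amino_acid[i], x$anticodon[i],
                x$copy_number[i], paste(x$codons[[i]], collapse = " ")))
  invisible(x)
}

#' Read a tRNA isoacceptor configuration file
#'
#' Plain-text tab-separated configuration, one isoacceptor per line:
#' columns \code{anticodon}, \code{amino_acid} (one letter),
#' \code{copy_number}, \code{codons} (comma-separated decoded codons;
#' \code{"auto"} applies \code{\link{wobble_codons}}). Lines starting with
#' \code{#} are comments.
#'
#' @param path File path.
#' @return An \code{isoacceptor_map}.
#' @seealso \code{\link{mth_isoacceptors}} for the shipped
#'   \emph{M. thermautotrophicus} Ser/Arg configuration.
#' @export
read_isoacceptor_config <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("anticodon", "amino_acid", "copy_number", "codons")
  if (!all(need %in% names(tab)))
    stop("isoacceptor config must have columns: ", paste(need, collapse = ", "))
  codons <- lapply(seq_len(nrow(tab)), function(i) {
    if (identical(tab$codons[i], "auto")) wobble_codons(tab$anticodon[i])
    else toupper(strsplit(tab$codons[i], ",", fixed = TRUE)[[1]])
  })
  new_isoacceptor_map(toupper(tab$anticodon), tab$amino_acid,
                      tab$copy_number, codons)
}

#' Shipped isoacceptor inventory for M. thermautotrophicus Ser and Arg
#'
#' The serine and arginine tRNA gene complement of
#' \emph{Methanothermobacter thermautotrophicus} strain deltaH
#' (four tRNA-Ser and four tRNA-Arg genes; the tRNA-Ser-GGA gene is
#' duplicated): Ser GGA (TCC, TCT), Ser TGA (TCA, TCG), Ser GCT
#' (AGC, AGT), Arg GCG (CGC, CGT), Arg TCG (CGA, CGG), Arg CCT (AGG),
#' Arg TCT (AGA). Editable copy installed under
#' \code{system.file("extdata", "mth_isoacceptors.tsv", package = "codonreuse")}.
#'
#' @return An \code{isoacceptor_map}.
#' @export
mth_isoacceptors <- function() {
  read_isoacceptor_config(system.file("extdata", "mth_isoacceptors.tsv",
                                      package = "codonreuse", mustWork = TRUE))
}

#' Generic isoacceptor map for a set of families
#'
#' Builds a default decoding inventory from the wobble rules when no
#' organism-specific configuration is available: each 4-codon block gets a
#' G-wobble anticodon (reads NNC/NNT) and a T-wobble anticodon (reads
#' NNA/NNG); purine-ending doublets get separate C- and (modified,
#' A-restricted) T-wobble anticodons, so their two codons form distinct
#' groups; pyrimidine doublets get one G-wobble anticodon; Ile3 is split
#' \{ATC,ATT\} / \{ATA\} (the ATA decoder carries a modified C34).
#'
#' @param families List of \code{synonymous_family} objects.
#' @return An \code{isoacceptor_map} covering every codon of the families.
#' @export
generic_isoacceptors <- function(families) {
  ac <- character(); aa <- character(); cod <- list()
  for (fam in families) {
    thirds <- substr(fam$codons, 3L, 3L)
    stem <- unique(substr(fam$codons, 1L, 2L))
    groups <- list()
    py <- fam$codons[thirds %in% c("C", "T")]
    pu <- fam$codons[thirds %in% c("A", "G")]
    if (length(py)) groups <- c(groups, list(py))
    if (length(pu) == 2L && fam$degeneracy == 2L) {
      groups <- c(groups, as.list(pu))        # A/G doublet: split
    } else if (length(pu)) {
      if (fam$name == "Ile3") groups <- c(groups, as.list(pu))
      else groups <- c(groups, list(pu))
    }
    for (g in groups) {
      # representative anticodon: reverse complement of the first codon
      ac <- c(ac, revcomp_chr(g[1]))
      aa <- c(aa, fam$amino_acid)
      cod <- c(cod, list(g))
    }
  }
  new_isoacceptor_map(ac, aa, rep(1L, length(ac)), cod)
}

#' Co-tRNA groups within a synonymous family
#'
#' Partitions a family's codons into groups decoded by the same tRNA
#' isoacceptor (codons in one group can reuse each other's tRNA). Should
#' two anticodons share a codon, their groups are merged so the result is
#' always a partition.
#'
#' @param family A \code{synonymous_family}.
#' @param iso An \code{isoacceptor_map} covering the family's codons.
#' @return List of character vectors, pairwise disjoint, whose union is
#'   \code{family$codons}.
#' @examples
#' fams <- partition_families(standard_code(11))
#' cotrna_groups(fams$Ser2, mth_isoacceptors())  # list(c("AGC","AGT"))
#' @export
cotrna_groups <- function(family, iso) {
  hits <- lapply(iso$codons, intersect, x = family$codons)
  hits <- hits[lengths(hits) > 0L]
  uncovered <- setdiff(family$codons, unlist(hits))
  if (length(uncovered))
    stop("no decoding anticodon configured for codon(s): ",
         paste(uncovered, collapse = ", "), " of family ", family$name)
  # merge transitively overlapping anticodon read-sets into one group
  groups <- list()
  for (h in hits) {
    touch <- vapply(groups, function(g) length(intersect(g, h)) > 0L, logical(1))
    merged <- sort(unique(c(h, unlist(groups[touch]))))
    groups <- c(groups[!touch], list(merged))
  }
  groups[order(vapply(groups, `[`, "", 1L))]
}

#' Export families as a table
#'
#' @param families List of \code{synonymous_family} objects.
#' @return \code{data.frame} with columns \code{family}, \code{amino_acid},
#'   \code{degeneracy}, \code{codon}.
#' @export
families_table <- function(families) {
  do.call(rbind, lapply(families, function(f)
    data.frame(family = f$name, amino_acid = f$amino_acid,
               degeneracy = f$degeneracy, codon = f$codons,
               row.names = NULL)))
}
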