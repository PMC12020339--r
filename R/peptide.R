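# Peptide chemistry: average mass, pH-dependent net charge, tryptic digestion.
#
# Sequences are one-letter strings over the 20 standard residues; the
# lowercase token "c" denotes carbamidomethylated (alkylated) cysteine,
# whose thiol is blocked and therefore not ionizable.

# Average (not monoisotopic) residue masses in Da, standard values.
.residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  # carbamidomethyl-Cys: Cys + CH2CONH2 (+57.0513)
  c = 160.1901
)

.mass_water <- 18.0153

.split_residues <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single nonempty string", call. = FALSE)
  strsplit(sequence, "", fixed = TRUE)[[1L]]
}

.check_tokens <- function(tokens) {
  bad <- setdiff(unique(tokens), names(.residue_mass))
  if (length(bad))
    stop("unknown residue token(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  invisible(tokens)
}

#' Average molecular mass of a peptide
#'
#' Sums standard average residue masses and adds one water (18.02 Da).
#' The lowercase token \code{"c"} is carbamidomethylated cysteine.
#'
#' @param sequence One-letter residue string.
#' @return Average molecular mass in Da.
#' @examples
#' average_mass("RRRRRRRW")  # hepta-arginine + tryptophan, ~1297 Da
#' average_mass("G")         # free glycine, 75.07 Da
#' @export
average_mass <- function(sequence) {
  tokens <- .check_tokens(.split_residues(sequence))
  sum(.residue_mass[tokens]) + .mass_water
}

#' Default pKa table for net-charge calculation
#'
#' EMBOSS-style side-chain and terminal pKa values. Entries: \code{Nterm},
#' \code{Cterm} and the ionizable side chains K, R, H (basic) and
#' D, E, C, Y (acidic).
#'
#' @return Named numeric vector of pKa values.
#' @export
default_pka <- function() {
  c(Nterm = 9.0, Cterm = 3.1,
    K = 10.5, R = 12.5, H = 6.0,
    D = 3.65, E = 4.25, C = 8.3, Y = 10.07)
}

.basic_groups <- c("Nterm", "K", "R", "H")

#' Net charge of a peptide at a given pH
#'
#' Henderson--Hasselbalch sum over the N-terminal amine, C-terminal
#' carboxylate and ionizable side chains (K, R, H positive; D, E, C, Y
#' negative). Alkylated cysteine (\code{"c"}) contributes nothing.
#'
#' @param sequence One-letter residue string.
#' @param pH pH in [0, 14].
#' @param pka Named pKa table, see [default_pka()]. Partial overrides are
#'   merged into the defaults.
#' @return Net charge in elementary charges.
#' @examples
#' net_charge("RRRRRRRG", 7.0)
#' net_charge("RRRRRRRG", 3.8)
#' @export
net_charge <- function(sequence, pH, pka = default_pka()) {
  tokens <- .check_tokens(.split_residues(sequence))
  if (!is.numeric(pH) || length(pH) != 1L || pH < 0 || pH > 14)
    stop("pH must be a single value in [0, 14]", call. = FALSE)
  tab <- default_pka()
  tab[names(pka)] <- pka
  groups <- c("Nterm", "Cterm", tokens[tokens %in% names(tab)])
  pos <- groups %in% .basic_groups
  pk <- tab[groups]
  # protonated fraction of each group
  frac <- 1 / (1 + 10^(pH - pk))
  sum(ifelse(pos, frac, frac - 1))
}

#' Peptide specification
#'
#' Bundles a peptide sequence with its derived average mass and a net-charge
#' function of pH.
#'
#' @param name Label.
#' @param sequence One-letter residue string (lowercase \code{"c"} =
#'   alkylated cysteine).
#' @param pka pKa table passed to [net_charge()].
#' @return An object of class \code{"peptide_spec"} with fields \code{name},
#'   \code{sequence}, \code{mass} (Da) and \code{charge_at} (function of pH).
#' @export
peptide_spec <- function(name, sequence, pka = default_pka()) {
  mass <- average_mass(sequence)
  structure(
    list(name = name, sequence = sequence, mass = mass,
         charge_at = function(pH) net_charge(sequence, pH, pka)),
    class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("Peptide %s: %s\n", x$name, x$sequence))
  cat(sprintf("  average mass: %.2f Da\n", x$mass))
  cat(sprintf("  net charge:   %+.2f (pH 7.0), %+.2f (pH 3.8)\n",
              x$charge_at(7.0), x$charge_at(3.8)))
  invisible(x)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the following residue is
#' proline. Fragments concatenate back to the input sequence exactly.
#'
#' @param protein_sequence One-letter residue string.
#' @param name Base label; fragments are named \code{<name>_f1, ...} in
#'   N-to-C order.
#' @return List of [peptide_spec()] objects in N-to-C order.
#' @examples
#' vapply(tryptic_digest("AAKAA"), `[[`, "", "sequence")   # "AAK" "AA"
#' vapply(tryptic_digest("AAKPAA"), `[[`, "", "sequence")  # "AAKPAA"
#' @export
tryptic_digest <- function(protein_sequence, name = "peptide") {
  tokens <- .check_tokens(.split_residues(protein_sequence))
  n <- length(tokens)
  cut <- which(tokens %in% c("K", "R"))
  cut <- cut[cut < n & tokens[cut + 1L] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  frags <- mapply(function(s, e) paste(tokens[s:e], collapse = ""),
                  starts, ends)
  lapply(seq_along(frags), function(i)
    peptide_spec(sprintf("%s_f%d", name, i), frags[[i]]))
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper returning a named character vector of uppercase sequences.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("seqinr", quietly = TRUE)) {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               seqonly = FALSE)
    out <- toupper(vapply(seqs, function(s) as.character(s)[1L], ""))
    names(out) <- vapply(seqs, function(s) attr(s, "name"), "")
    return(out)
  }
  # minimal fallback parser for plain single-line-or-wrapped FASTA
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(hdr)
  seqs <- tapply(lines[!hdr], idx[!hdr], paste, collapse = "")
  out <- toupper(unname(as.character(seqs)))
  names(out) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  out
}

#' Write a peptide table as TSV
#'
#' Columns: name, sequence, mass_Da, charge_pH7, charge_pH3.8.
#'
#' @param peptides List of [peptide_spec()] objects.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  tab <- data.frame(
    name = vapply(peptides, `[[`, "", "name"),
    sequence = vapply(peptides, `[[`, "", "sequence"),
    mass_Da = vapply(peptides, `[[`, 0, "mass"),
    charge_pH7 = vapply(peptides, function(p) p$charge_at(7.0), 0),
    charge_pH3.8 = vapply(peptides, function(p) p$charge_at(3.8), 0),
    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
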