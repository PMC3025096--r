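# Peptide chemistry core: monoisotopic residue masses, variable modifications,
# peptide mass / m-z arithmetic, in-silico tryptic digestion and peptide-to-
# protein site mapping.

# Monoisotopic masses of the 20 standard amino-acid residues (Da), plus the
# constants needed to turn a residue-mass sum into a peptide [M] and an m/z.
.RESIDUE_MASSES <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)
.PROTON_MASS <- 1.007276
.WATER_MASS <- 18.010565

.RESIDUE_THREE <- c(
  G = "Gly", A = "Ala", S = "Ser", P = "Pro", V = "Val", T = "Thr", C = "Cys",
  L = "Leu", I = "Ile", N = "Asn", D = "Asp", Q = "Gln", K = "Lys", E = "Glu",
  M = "Met", H = "His", F = "Phe", R = "Arg", Y = "Tyr", W = "Trp"
)

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) for the 20 standard amino-acid
#' residues (residue = amino acid minus water), as used throughout the
#' package's mass arithmetic.
#'
#' @return Named numeric vector keyed by one-letter residue code.
#' @export
#' @examples
#' amino_acid_masses()[["G"]]
amino_acid_masses <- function() .RESIDUE_MASSES

#' Physical constants for mass/charge arithmetic
#'
#' @return List with `proton` (1.007276 Da) and `water` (18.010565 Da).
#' @export
mass_constants <- function() list(proton = .PROTON_MASS, water = .WATER_MASS)

#' Define a variable modification
#'
#' A modification is a named mass delta restricted to a set of residues, e.g.
#' phosphorylation of Ser/Thr/Tyr (+79.966331 Da) or oxidation of Met
#' (+15.994915 Da).
#'
#' @param name Modification name.
#' @param delta Monoisotopic mass shift in Da; must be finite and nonzero.
#' @param residues Character vector of one-letter codes the modification may
#'   sit on.
#' @param position Positional rule: `"any"` (default) or `"protein-terminus"`.
#' @return Object of class `modification_spec`.
#' @export
#' @examples
#' modification_spec("phospho", 79.966331, c("S", "T", "Y"))
modification_spec <- function(name, delta, residues,
                              position = c("any", "protein-terminus")) {
  position <- match.arg(position)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(delta) || delta == 0) {
    stop("modification '", name, "': mass delta must be finite and nonzero",
         call. = FALSE)
  }
  residues <- unique(toupper(residues))
  unknown <- setdiff(residues, names(.RESIDUE_MASSES))
  if (length(unknown) > 0) {
    stop("modification '", name, "': unknown residue code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, delta = delta, residues = residues,
                 position = position),
            class = "modification_spec")
}

#' @export
print.modification_spec <- function(x, ...) {
  cat(sprintf("<modification> %s %+0.6f Da on {%s}\n",
              x$name, x$delta, paste(x$residues, collapse = ",")))
  invisible(x)
}

#' Built-in modifications
#'
#' `mod_phospho()` is phosphorylation of Ser/Thr/Tyr (+79.966331 Da);
#' `mod_oxidation()` is oxidation of Met (+15.994915 Da). These are the two
#' variable modifications used for lens phosphopeptide searches.
#'
#' @return A `modification_spec`.
#' @export
mod_phospho <- function() modification_spec("phospho", 79.966331, c("S", "T", "Y"))

#' @rdname mod_phospho
#' @export
mod_oxidation <- function() modification_spec("oxidation", 15.994915, "M")

#' Read modification definitions from a TSV config file
#'
#' Expects columns `name`, `delta`, `residues` (residues as a concatenated
#' string such as `"STY"`).
#'
#' @param path Path to the TSV file.
#' @return Named list of `modification_spec` objects.
#' @export
read_modifications <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("name", "delta", "residues")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("modification config lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  specs <- purrr::pmap(tab[need], function(name, delta, residues) {
    modification_spec(name, as.numeric(delta),
                      strsplit(residues, "")[[1]])
  })
  stats::setNames(specs, tab$name)
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0) {
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, names(.RESIDUE_MASSES))
  if (length(bad) > 0) {
    stop("unknown residue code(s) in sequence: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  chars
}

#' Construct a modified peptide
#'
#' The unit of mass and m/z computation: a peptide sequence with positioned
#' modifications and a charge state.
#'
#' @param sequence One-letter amino-acid string.
#' @param modifications List of modifications, each a list with `position`
#'   (1-based within the peptide) and `spec` (a [modification_spec()]).
#' @param charge Positive integer charge state.
#' @return Object of class `modified_peptide`.
#' @export
#' @examples
#' modified_peptide("RPFFPFHSPSR",
#'                  list(list(position = 8, spec = mod_phospho())),
#'                  charge = 3)
modified_peptide <- function(sequence, modifications = list(), charge = 2L) {
  chars <- .check_sequence(sequence)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be >= 1", call. = FALSE)
  for (m in modifications) {
    if (!all(c("position", "spec") %in% names(m)) ||
        !inherits(m$spec, "modification_spec")) {
      stop("each modification must be list(position=, spec=modification_spec)",
           call. = FALSE)
    }
    pos <- m$position
    if (pos < 1 || pos > length(chars)) {
      stop("modification position ", pos, " outside peptide of length ",
           length(chars), call. = FALSE)
    }
    if (!chars[pos] %in% m$spec$residues) {
      stop("modification '", m$spec$name, "' not allowed on residue '",
           chars[pos], "' at position ", pos, call. = FALSE)
    }
  }
  structure(list(sequence = sequence, modifications = modifications,
                 charge = charge),
            class = "modified_peptide")
}

#' @export
print.modified_peptide <- function(x, ...) {
  mods <- if (length(x$modifications) == 0) "none" else {
    paste(vapply(x$modifications,
                 function(m) paste0(m$spec$name, "@", m$position), ""),
          collapse = ", ")
  }
  cat(sprintf("<peptide> %s (%d+), mods: %s\n", x$sequence, x$charge, mods))
  invisible(x)
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus all modification deltas;
#' independent of charge.
#'
#' @param peptide A [modified_peptide()], or a plain sequence string.
#' @param modifications For a plain string, an optional modification list as in
#'   [modified_peptide()].
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("GG") # 132.05349
peptide_mass <- function(peptide, modifications = list()) {
  if (inherits(peptide, "modified_peptide")) {
    modifications <- peptide$modifications
    peptide <- peptide$sequence
  }
  chars <- .check_sequence(peptide)
  # re-validate positions/residues when called with a raw string
  for (m in modifications) {
    if (m$position < 1 || m$position > length(chars) ||
        !chars[m$position] %in% m$spec$residues) {
      stop("modification '", m$spec$name, "' invalid at position ", m$position,
           call. = FALSE)
    }
  }
  deltas <- sum(vapply(modifications, function(m) m$spec$delta, 0))
  sum(.RESIDUE_MASSES[chars]) + .WATER_MASS + deltas
}

#' Convert a neutral mass to m/z, and back
#'
#' `mass_to_mz(mass, z)` returns `(mass + z * proton) / z`; `mz_to_mass` is its
#' exact inverse.
#'
#' @param mass Neutral monoisotopic mass (Da), > 0.
#' @param charge Integer charge >= 1.
#' @return m/z in Thomson.
#' @export
#' @examples
#' mass_to_mz(1000, 1) # 1001.007276
mass_to_mz <- function(mass, charge) {
  if (any(mass <= 0)) stop("mass must be > 0", call. = FALSE)
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be an integer >= 1", call. = FALSE)
  }
  (mass + charge * .PROTON_MASS) / charge
}

#' @rdname mass_to_mz
#' @param mz m/z value (Th).
#' @export
mz_to_mass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  mz * charge - charge * .PROTON_MASS
}

#' m/z of a modified peptide at its charge state
#'
#' @param peptide A [modified_peptide()].
#' @return m/z in Thomson.
#' @export
peptide_mz <- function(peptide) {
  stopifnot(inherits(peptide, "modified_peptide"))
  mass_to_mz(peptide_mass(peptide), peptide$charge)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and returns
#' every fragment carrying up to `missed_cleavages` internal missed cleavage
#' sites, with 1-based inclusive coordinates in the parent protein. Protein
#' N-terminal Met is retained (numbering includes the initiator Met).
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param missed_cleavages Maximum number of missed cleavages (default 2, the
#'   usual search setting).
#' @return Tibble with columns `peptide`, `start`, `end`, `missed`.
#' @export
#' @examples
#' tryptic_digest("MKRPFFR", missed_cleavages = 0)
tryptic_digest <- function(sequence, missed_cleavages = 2L) {
  chars <- .check_sequence(sequence)
  missed_cleavages <- as.integer(missed_cleavages)
  if (is.na(missed_cleavages) || missed_cleavages < 0) {
    stop("missed_cleavages must be >= 0", call. = FALSE)
  }
  n <- length(chars)
  # cut points: after position i when chars[i] in {K,R} and chars[i+1] != P
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts == n | chars[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts[cuts < n], n)  # fragment i spans (bounds[i], bounds[i+1]]
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  k <- length(starts)
  out <- vector("list", 0L)
  for (mc in 0:min(missed_cleavages, k - 1L)) {
    i <- seq_len(k - mc)
    out[[length(out) + 1L]] <- tibble::tibble(
      start = starts[i], end = ends[i + mc], missed = mc
    )
  }
  res <- dplyr::bind_rows(out)
  res$peptide <- substring(sequence, res$start, res$end)
  dplyr::arrange(res[, c("peptide", "start", "end", "missed")],
                 .data$start, .data$missed)
}

#' Map a within-peptide position to a protein-level site designation
#'
#' Given a digest fragment's start coordinate and a 1-based position inside the
#' peptide, returns the field-standard designation, e.g. `"Ser-19"`.
#'
#' @param peptide Peptide sequence of the fragment.
#' @param start 1-based start of the fragment in the parent protein.
#' @param position 1-based position within the peptide.
#' @return Designation string (three-letter residue name, hyphen, protein
#'   position).
#' @export
#' @examples
#' annotate_site("RPFFPFHSPSR", start = 12, position = 8) # "Ser-19"
annotate_site <- function(peptide, start, position) {
  chars <- .check_sequence(peptide)
  if (position < 1 || position > length(chars)) {
    stop("position ", position, " outside peptide of length ", length(chars),
         call. = FALSE)
  }
  paste0(.RESIDUE_THREE[[chars[position]]], "-", start + position - 1L)
}

#' Parse a site designation
#'
#' Splits `"Ser-19"` into the residue (three-letter and one-letter) and the
#' protein position.
#'
#' @param designation Designation string(s) such as `"Ser-19"`.
#' @return Tibble with `residue3`, `residue1`, `position`.
#' @export
parse_designation <- function(designation) {
  m <- stringr::str_match(designation, "^([A-Za-z]{3})-(\\d+)$")
  if (any(is.na(m[, 1]))) {
    bad <- designation[is.na(m[, 1])]
    stop("unparseable site designation(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  res3 <- m[, 2]
  lut <- stats::setNames(names(.RESIDUE_THREE), .RESIDUE_THREE)
  res1 <- unname(lut[res3])
  if (any(is.na(res1))) {
    stop("unknown residue name(s) in designation: ",
         paste(unique(res3[is.na(res1)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(residue3 = res3, residue1 = res1,
                 position = as.integer(m[, 3]))
}

#' Read protein sequences from FASTA
#'
#' Accession is the header token up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
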