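#' @useDynLib argphos, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# one-letter codes accepted by the bead model
.aa_codes <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# average residue (monomer) masses, Da; water added once per chain
.aa_mass <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)

#' Default pKa table for side-chain and terminal ionisation
#'
#' Used by [assign_charges()]. Values are for the free residues in a
#' disordered chain context.
#'
#' @export
default_pka <- c(D = 4.0, E = 4.4, H = 6.3, K = 10.4, R = 12.0,
                 NT = 8.0, CT = 3.6)

#' Mature histatin 5 wild-type sequence
#'
#' The 24-residue cationic saliva peptide (3 Arg, 4 Lys, 7 His, 1 Asp,
#' 1 Glu; net charge +5 at pH 8.4 with neutral His).
#'
#' @export
hst5_sequence <- "DSHAKRHHGYKRKFHEKHHSHRGY"

#' Build a bead-chain topology from a protein sequence
#'
#' Each residue becomes one bead of the given radius carrying the charge
#' of the corresponding amino acid; the N- and C-termini are kept as
#' explicit zero-radius charge sites co-located with the first and last
#' bead so that their charges are accounted for.
#'
#' @param source an inline one-letter sequence string, or the path to a
#'   FASTA file (first record used)
#' @param name label for the chain; defaults to the FASTA header or
#'   `"chain"`
#' @param bead_radius bead radius in Angstrom (default 2)
#' @param pH pH at which charges are assigned (default 8.4)
#' @param scheme charge scheme passed to [assign_charges()]
#' @return an object of class `chain_topology`: a data frame with one row
#'   per charge site (columns `code`, `radius`, `charge`, `is_arginine`,
#'   `is_terminal`) plus attributes `name`, `bonds` (2-column matrix of
#'   bonded residue-bead indices), `net_charge` and `mw` (monomer mass,
#'   Da).
#' @examples
#' wt <- load_sequence(hst5_sequence, name = "Hst5 WT")
#' attr(wt, "net_charge")  # +5 at pH 8.4
#' @export
load_sequence <- function(source, name = NULL, bead_radius = 2,
                          pH = 8.4, scheme = "integer") {
  stopifnot(is.character(source), length(source) == 1)
  if (file.exists(source)) {
    fas <- seqinr::read.fasta(source, seqtype = "AA", as.string = TRUE)
    if (length(fas) == 0) stop("empty FASTA file: ", source)
    if (is.null(name)) name <- names(fas)[1]
    source <- toupper(as.character(fas[[1]]))
  }
  seq <- toupper(gsub("[[:space:]*]", "", source))
  if (nchar(seq) == 0) stop("empty sequence")
  res <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(res), .aa_codes)
  if (length(bad) > 0)
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  if (length(res) < 2) stop("chain must contain at least 2 residues")
  if (is.null(name)) name <- "chain"

  code <- c("NT", res, "CT")
  topo <- data.frame(
    code = code,
    radius = ifelse(code %in% c("NT", "CT"), 0, bead_radius),
    charge = 0,
    is_arginine = code == "R",
    is_terminal = code %in% c("NT", "CT"),
    stringsAsFactors = FALSE
  )
  n <- length(res)
  attr(topo, "name") <- name
  # bonds between consecutive residue beads (rows 2..n+1 of the table)
  attr(topo, "bonds") <- cbind(2:n, 3:(n + 1))
  attr(topo, "mw") <- sum(.aa_mass[res]) + 18.0153
  class(topo) <- c("chain_topology", "data.frame")
  assign_charges(topo, pH = pH, scheme = scheme)
}

#' Assign per-bead charges at a given pH
#'
#' Two schemes are offered. `"integer"` gives whole-valence charges:
#' Asp/Glu -1, Lys/Arg +1, His +1 below its pKa and 0 above, N-terminus
#' +1, C-terminus -1. `"average"` assigns fractional
#' Henderson--Hasselbalch charges from a pKa table.
#'
#' @param topology a `chain_topology`
#' @param pH pH in `[0, 14]`
#' @param scheme `"integer"` or `"average"`
#' @param pka named pKa vector (see [default_pka])
#' @return the topology with updated `charge` column and `net_charge`
#'   attribute; idempotent at fixed `(pH, scheme)`
#' @export
assign_charges <- function(topology, pH = 8.4, scheme = c("integer", "average"),
                           pka = default_pka) {
  stopifnot(inherits(topology, "chain_topology"), pH >= 0, pH <= 14)
  scheme <- match.arg(scheme)
  code <- topology$code
  q <- numeric(length(code))
  if (scheme == "integer") {
    q[code %in% c("D", "E", "CT")] <- -1
    q[code %in% c("K", "R", "NT")] <- +1
    q[code == "H"] <- if (pH < pka[["H"]]) +1 else 0
  } else {
    hh_base <- function(pk) 1 / (1 + 10^(pH - pk))        # cationic groups
    hh_acid <- function(pk) -1 / (1 + 10^(pk - pH))       # anionic groups
    q[code == "D"] <- hh_acid(pka[["D"]])
    q[code == "E"] <- hh_acid(pka[["E"]])
    q[code == "CT"] <- hh_acid(pka[["CT"]])
    q[code == "H"] <- hh_base(pka[["H"]])
    q[code == "K"] <- hh_base(pka[["K"]])
    q[code == "R"] <- hh_base(pka[["R"]])
    q[code == "NT"] <- hh_base(pka[["NT"]])
  }
  topology$charge <- q
  attr(topology, "net_charge") <- sum(q)
  attr(topology, "pH") <- pH
  attr(topology, "scheme") <- scheme
  topology
}

#' Construct histatin 5 sequence variants
#'
#' The arginine-content variants swap Arg and Lys so that the linear
#' charge density of the wild type is conserved exactly; `"0K"` replaces
#' all Lys by Ala (lowering the net charge); `"shuffle"` permutes the
#' residues reproducibly.
#'
#' @param topology a `chain_topology` (typically the Hst5 wild type)
#' @param spec one of `"0R"` (all R->K), `"1R"` (keep one Arg),
#'   `"2R"` (keep two Arg), `"Ra"`/`"Rb"`/`"Rc"` (keep the single
#'   N-proximal / middle / C-proximal Arg), `"0K"` (all K->A),
#'   `"shuffle"`
#' @param seed integer seed, used by `"shuffle"`
#' @param keep for `"1R"`/`"2R"`: which Arg occurrences (counted from the
#'   N-terminus) to keep. Defaults: middle Arg for `"1R"`, first and last
#'   for `"2R"`. Exposed so that any reading of the published variant
#'   table can be encoded.
#' @return a re-charged `chain_topology` with an updated name
#' @export
make_variant <- function(topology, spec, seed = 1L, keep = NULL) {
  stopifnot(inherits(topology, "chain_topology"))
  res <- topology$code[!topology$is_terminal]
  arg_pos <- which(res == "R")
  keep_n <- switch(spec, "1R" = 1L, "2R" = 2L, Ra = 1L, Rb = 1L, Rc = 1L, NA_integer_)
  if (!is.na(keep_n) && length(arg_pos) < keep_n)
    stop("variant '", spec, "' requires at least ", keep_n,
         " Arg; sequence has ", length(arg_pos))
  new <- res
  if (spec == "0R") {
    new[arg_pos] <- "K"
  } else if (spec %in% c("1R", "2R", "Ra", "Rb", "Rc")) {
    keep <- if (!is.null(keep)) keep else switch(spec,
      "1R" = ceiling(length(arg_pos) / 2),
      "2R" = c(1L, length(arg_pos)),
      Ra = 1L,
      Rb = ceiling(length(arg_pos) / 2),
      Rc = length(arg_pos))
    if (any(keep > length(arg_pos)))
      stop("'keep' indexes more Arg than the sequence has")
    new[arg_pos[-keep]] <- "K"
  } else if (spec == "0K") {
    new[which(res == "K")] <- "A"
  } else if (spec == "shuffle") {
    new <- with_seed(seed, sample(res))
  } else {
    stop("unknown variant spec: ", spec)
  }
  out <- load_sequence(paste(new, collapse = ""),
                       name = paste(attr(topology, "name"), spec),
                       bead_radius = max(topology$radius),
                       pH = attr(topology, "pH") %||% 8.4,
                       scheme = attr(topology, "scheme") %||% "integer")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.chain_topology <- function(x, ...) {
  res <- x$code[!x$is_terminal]
  cat(sprintf("<chain_topology> %s: %d residues, net charge %+.3g (pH %s, %s scheme)\n",
              attr(x, "name"), length(res), attr(x, "net_charge"),
              format(attr(x, "pH")), attr(x, "scheme")))
  cat("  ", paste(res, collapse = ""), "\n")
  cat(sprintf("   %d Arg, %d Lys, MW %.1f Da\n",
              sum(res == "R"), sum(res == "K"), attr(x, "mw")))
  invisible(x)
}

#' Write a topology's sequence as FASTA
#'
#' @param topology a `chain_topology`
#' @param path output file
#' @export
write_fasta <- function(topology, path) {
  res <- topology$code[!topology$is_terminal]
  seqinr::write.fasta(paste(res, collapse = ""),
                      names = attr(topology, "name"), file.out = path)
  invisible(path)
}
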