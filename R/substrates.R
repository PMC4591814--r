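# Assay substrates: primer-template duplexes with optional lesion and
# optional downstream oligo forming a nick.
#
# Coordinate conventions used throughout the package:
#   * Sequences are stored 5'->3'.
#   * Template bases are counted 1..L from the 3' end (the order in which
#     an advancing primer copies them).
#   * N indices: N0 is the unextended primer (n0 nt); Ni is the product
#     extended by i nucleotides, so product length in nt = n0 + i.
#     K = template length - primer length is the number of extendable
#     positions; NK is full length.

LESION_KINDS <- c("NONE", "TG_5S")

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement of a plain `ACGT` string, both input
#' and output written 5'->3'.
#'
#' @param sequence Character scalar over `A`, `C`, `G`, `T` (5'->3').
#' @return Character scalar, the reverse complement (5'->3').
#' @examples
#' reverse_complement("CACT")  # "AGTG"
#' @export
reverse_complement <- function(sequence) {
  check_dna(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

check_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(sequence) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop("invalid ", what, ": characters outside {A,C,G,T}", call. = FALSE)
  invisible(sequence)
}

#' Construct an oligonucleotide
#'
#' An oligo is a labelled DNA sequence, stored 5'->3', with optional
#' lesion annotations. The only lesion kind currently modelled is
#' `"TG_5S"`, a (5S)-thymine glycol, which must annotate a `T` base and
#' pairs as T for annealing purposes (it is a damaged thymine; the
#' undamaged control carries T at the same position).
#'
#' @param label Name for the oligo.
#' @param sequence DNA string over `ACGT`. If `orientation = "3to5"` the
#'   string is taken as written 3'->5' (the way bottom-strand templates
#'   are often printed) and is reversed on storage; lesion positions are
#'   remapped accordingly.
#' @param lesions Integer vector of 1-based lesion positions, in the
#'   coordinates of `sequence` as supplied.
#' @param lesion_kinds Character vector parallel to `lesions`; defaults
#'   to `"TG_5S"` for every position.
#' @param orientation Either `"5to3"` (default) or `"3to5"`.
#' @return An object of class `tls_oligo` with fields `label`,
#'   `sequence` (5'->3') and `lesions` (named character vector: names
#'   are positions in the stored sequence, values are lesion kinds).
#' @export
oligo <- function(label, sequence, lesions = integer(0),
                  lesion_kinds = rep("TG_5S", length(lesions)),
                  orientation = c("5to3", "3to5")) {
  orientation <- match.arg(orientation)
  check_dna(sequence)
  lesions <- as.integer(lesions)
  if (length(lesion_kinds) != length(lesions))
    stop("lesion_kinds must be parallel to lesions", call. = FALSE)
  if (!all(lesion_kinds %in% setdiff(LESION_KINDS, "NONE")))
    stop("unknown lesion kind; supported: ",
         paste(setdiff(LESION_KINDS, "NONE"), collapse = ", "), call. = FALSE)
  len <- nchar(sequence)
  if (any(lesions < 1L | lesions > len))
    stop("lesion position outside 1..", len, call. = FALSE)
  if (orientation == "3to5") {
    sequence <- rev_string(sequence)
    lesions <- len - lesions + 1L
  }
  bases <- if (length(lesions)) substring(sequence, lesions, lesions)
           else character(0)
  bad <- lesion_kinds == "TG_5S" & bases != "T"
  if (length(bad) && any(bad))
    stop("TG_5S may only annotate a T base (position ",
         paste(lesions[bad], collapse = ", "), ")", call. = FALSE)
  les <- structure(lesion_kinds, names = as.character(lesions))
  structure(list(label = as.character(label), sequence = sequence,
                 lesions = les),
            class = "tls_oligo")
}

rev_string <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

as_oligo <- function(x, label, orientation = "5to3") {
  if (inherits(x, "tls_oligo")) return(x)
  oligo(label, x, orientation = orientation)
}

#' @export
print.tls_oligo <- function(x, ...) {
  cat(sprintf("<oligo %s> 5'-%s-3' (%d nt)\n", x$label, x$sequence,
              nchar(x$sequence)))
  if (length(x$lesions))
    cat("  lesions:", paste(sprintf("%s@%s", x$lesions, names(x$lesions)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a primer-template substrate
#'
#' Validates that the primer anneals flush to the template's 3' end
#' (the primer must be the exact reverse complement of the template's
#' 3'-terminal bases, with a TG_5S lesion pairing as T) and, when a
#' downstream oligo is supplied, that it is the reverse complement of a
#' contiguous 5'-terminal block of the template. The substrate records
#' the N-coordinate geometry: `n0` (primer length), `K` (extendable
#' positions), `lesion_N` (lesion position in N coordinates, if any) and
#' `nick_N` (first position at which the advancing primer meets the
#' downstream oligo, if any).
#'
#' @param primer,template,downstream `tls_oligo` objects or plain
#'   character sequences. `downstream` may be `NULL`.
#' @param template_orientation Orientation of `template` when it is
#'   given as a character string (`"5to3"` or `"3to5"`); bottom-strand
#'   templates are conventionally printed 3'->5' and the explicit flag
#'   avoids silent reverse-complement mistakes.
#' @param name Optional substrate name; defaults to the template label.
#' @return An object of class `tls_substrate`.
#' @examples
#' s <- assemble_substrate("CACTGACTGTATGATG",
#'                         "GTGACTGACATACTACTTCTACGACTGCTC",
#'                         template_orientation = "3to5")
#' s$K  # 14 extendable positions
#' @export
assemble_substrate <- function(primer, template, downstream = NULL,
                               template_orientation = c("5to3", "3to5"),
                               name = NULL) {
  template_orientation <- match.arg(template_orientation)
  primer <- as_oligo(primer, "primer")
  template <- as_oligo(template, "template", orientation = template_orientation)
  if (!is.null(downstream)) downstream <- as_oligo(downstream, "downstream")

  n0 <- nchar(primer$sequence)
  len <- nchar(template$sequence)
  if (len <= n0)
    stop("template must be longer than primer", call. = FALSE)
  K <- len - n0

  tail3 <- substring(template$sequence, len - n0 + 1L, len)
  if (reverse_complement(tail3) != primer$sequence)
    stop("annealing error: primer is not the reverse complement of the ",
         "template's 3'-terminal ", n0, " bases", call. = FALSE)

  nick_N <- NULL
  if (!is.null(downstream)) {
    dlen <- nchar(downstream$sequence)
    if (dlen + n0 > len)
      stop("annealing error: downstream oligo does not fit on the template",
           call. = FALSE)
    head5 <- substring(template$sequence, 1L, dlen)
    if (reverse_complement(head5) != downstream$sequence)
      stop("annealing error: downstream oligo is not the reverse complement ",
           "of the template's 5'-terminal ", dlen, " bases", call. = FALSE)
    nick_N <- (len - n0 - dlen) + 1L
  }

  lesion_N <- NULL
  if (length(template$lesions)) {
    pos5 <- as.integer(names(template$lesions))
    from3 <- len - pos5 + 1L          # template base index from the 3' end
    n_idx <- from3 - n0
    keep <- n_idx >= 1L & n_idx <= K
    if (any(!keep))
      warning("lesion under the primer or beyond the template; ignored for N map")
    if (sum(keep) > 1L)
      stop("at most one lesion within the extendable region is supported",
           call. = FALSE)
    if (any(keep)) lesion_N <- n_idx[keep]
  }

  structure(list(
    name = if (is.null(name)) template$label else as.character(name),
    primer = primer, template = template, downstream = downstream,
    n0 = n0, K = K, lesion_N = lesion_N, nick_N = nick_N
  ), class = "tls_substrate")
}

#' @export
print.tls_substrate <- function(x, ...) {
  cat(sprintf("<substrate %s> n0=%d, K=%d (products N0=%d..N%d=%d nt)\n",
              x$name, x$n0, x$K, x$n0, x$K, x$n0 + x$K))
  if (!is.null(x$lesion_N)) cat("  lesion at N", x$lesion_N, "\n", sep = "")
  if (!is.null(x$nick_N)) cat("  nick met at N", x$nick_N, "\n", sep = "")
  invisible(x)
}

#' Per-position map of a substrate
#'
#' One row per extendable position N1..NK giving the template base
#' copied at that insertion step, the Watson-Crick correct incoming
#' dNTP, the lesion kind at the position and whether the position lies
#' at or beyond the nick (strand displacement required).
#'
#' @param substrate A `tls_substrate`.
#' @return `data.frame` with columns `N`, `template_base`,
#'   `correct_dNTP`, `lesion`, `at_nick`.
#' @export
position_map <- function(substrate) {
  stopifnot(inherits(substrate, "tls_substrate"))
  len <- nchar(substrate$template$sequence)
  n0 <- substrate$n0
  K <- substrate$K
  N <- seq_len(K)
  pos5 <- len - (n0 + N) + 1L         # stored-sequence index of base at Ni
  base <- substring(substrate$template$sequence, pos5, pos5)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  dNTP <- paste0("d", comp[base], "TP")
  lesion <- rep("NONE", K)
  if (length(substrate$template$lesions)) {
    lp <- as.integer(names(substrate$template$lesions))
    hit <- match(pos5, lp)
    lesion[!is.na(hit)] <- unname(substrate$template$lesions[hit[!is.na(hit)]])
  }
  at_nick <- if (is.null(substrate$nick_N)) rep(FALSE, K) else N >= substrate$nick_N
  data.frame(N = N, template_base = base, correct_dNTP = unname(dNTP),
             lesion = lesion, at_nick = at_nick,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Sequences of the characterized zebrafish POLN bypass assay.  The
# 30-mer template is printed 3'->5' with a variable first template base
# X (T, G, or 5S-thymine glycol on T); primers of 14/15/16 nt anneal to
# its 3' end, placing X at N3/N2/N1 respectively.  The downstream
# 14-mer forms a nick flush with the extended 16-mer primer.
TLS_PRIMER_16 <- "CACTGACTGTATGATG"
TLS_TEMPLATE_3TO5 <- "GTGACTGACATACTAC%sTCTACGACTGCTC"  # %s = X at base 17
TLS_DOWNSTREAM <- "AAGATGCTGACGAG"
TLS_X_POS_3TO5 <- 17L

#' Reference substrates of the zebrafish POLN bypass assay
#'
#' The eight primer-template combinations used to characterize
#' translesion synthesis and strand displacement by zebrafish POLN:
#' 14-, 15- and 16-mer primers on a 30-mer template whose first variable
#' base X is T, G or a (5S)-thymine glycol (Tg), plus a nicked X=T
#' substrate carrying a downstream 14-mer. Names follow the
#' "primer-length/X" convention, e.g. `"14/Tg"`.
#'
#' @return Named list of eight `tls_substrate` objects:
#'   `14/T`, `14/Tg`, `15/T`, `15/Tg`, `16/T`, `16/G`, `16/Tg`,
#'   `nicked-16/T`.
#' @export
tls_substrates <- function() {
  make_template <- function(x_base, lesion) {
    seq3to5 <- sprintf(TLS_TEMPLATE_3TO5, x_base)
    oligo(paste0("template-", if (lesion) "Tg" else x_base), seq3to5,
          lesions = if (lesion) TLS_X_POS_3TO5 else integer(0),
          orientation = "3to5")
  }
  primers <- list(
    `14` = oligo("primer-14", substr(TLS_PRIMER_16, 1L, 14L)),
    `15` = oligo("primer-15", substr(TLS_PRIMER_16, 1L, 15L)),
    `16` = oligo("primer-16", TLS_PRIMER_16)
  )
  templates <- list(
    T  = make_template("T", FALSE),
    G  = make_template("G", FALSE),
    Tg = make_template("T", TRUE)
  )
  combos <- list(c("14", "T"), c("14", "Tg"), c("15", "T"), c("15", "Tg"),
                 c("16", "T"), c("16", "G"), c("16", "Tg"))
  out <- lapply(combos, function(co) {
    assemble_substrate(primers[[co[1L]]], templates[[co[2L]]],
                       name = paste0(co[1L], "/", co[2L]))
  })
  names(out) <- vapply(combos, function(co) paste0(co[1L], "/", co[2L]), "")
  out[["nicked-16/T"]] <- assemble_substrate(
    primers[["16"]], templates[["T"]],
    downstream = oligo("downstream-14", TLS_DOWNSTREAM),
    name = "nicked-16/T")
  out
}
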