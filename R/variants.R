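## Variant identity and tokens.
##
## The simulator never materialises a reference sequence: only mutated
## positions and which of the three possible alternate alleles each molecule
## carries matter.  Alternate alleles are labelled C/G/T under an A-reference
## convention so that tokens look like ordinary variant calls.  Internally a
## variant is a single integer code, position * 3 + allele index, which keeps
## haplotypes as plain sorted integer vectors.

ALT_ALLELES <- c("C", "G", "T")

#' Encode variants as integer codes
#'
#' A variant is identified by its 0-based genome position and its alternate
#' allele (one of `"C"`, `"G"`, `"T"`; the abstract reference base is labelled
#' `"A"` at every site).  Equal (position, allele) pairs denote the same
#' variant everywhere in a run.
#'
#' @param position Integer vector of 0-based positions in `[0, L)`.
#' @param allele Character vector of alternate alleles, recycled to the length
#'   of `position`.
#' @return Integer variant codes.
#' @seealso [variant_token()] for the printable `"pos:allele"` form.
#' @export
#' @examples
#' variant_code(3242, "G")
#' variant_token(variant_code(3242, "G"))
variant_code <- function(position, allele = "C") {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 0)) {
    stop("'position' must be a non-negative integer", call. = FALSE)
  }
  ai <- match(rep_len(as.character(allele), length(position)), ALT_ALLELES)
  if (anyNA(ai)) {
    stop("'allele' must be one of ", paste(ALT_ALLELES, collapse = ", "),
         " (reference base is labelled 'A')", call. = FALSE)
  }
  position * 3L + (ai - 1L)
}

#' @rdname variant_code
#' @param code Integer variant codes as produced by [variant_code()].
#' @export
variant_token <- function(code) {
  code <- as.integer(code)
  if (!length(code)) return(character(0))
  paste0(code %/% 3L, ":", ALT_ALLELES[code %% 3L + 1L])
}

#' @rdname variant_code
#' @param token Character vector of `"pos:allele"` tokens (0-based positions).
#' @export
parse_variant_token <- function(token) {
  parts <- strsplit(as.character(token), ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed variant token: ", token[bad][1L], call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  if (anyNA(pos)) stop("malformed variant token position", call. = FALSE)
  variant_code(pos, vapply(parts, `[`, "", 2L))
}
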