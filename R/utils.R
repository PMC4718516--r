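# Identifier normalization and shared small helpers.

#' Normalize gene identifiers
#'
#' Gene symbols are uppercased and stripped of surrounding whitespace at every
#' package boundary, so case-variant spellings of the same symbol can never
#' cause a silent set-intersection miss.
#'
#' @param x Character vector of gene identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' norm_gene_id(c("App", " bace1 "))
norm_gene_id <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Normalize miRNA identifiers
#'
#' Published miRNA names vary in dialect ("miR-29b-1" vs "miR-29b1").
#' Names are lowercased and a hyphen separating a letter from a trailing copy
#' digit is removed, so both dialects map to one id. A hyphen between two
#' digits (as in mir-101-1) is kept: removing it would merge distinct
#' families (mir-101-1 vs mir-1011).
#'
#' @param x Character vector of miRNA identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' norm_mirna_id(c("miR-29b-1", "miR-29b1", "miR-101-1"))
norm_mirna_id <- function(x) {
  x <- tolower(trimws(as.character(x)))
  sub("([a-z])-([0-9]+)$", "\\1\\2", x)
}

# Stop with a classed condition; all user-facing validation errors go
# through here so tests can assert on class "dgnet_error".
dg_stop <- function(msg, class = "dgnet_error") {
  rlang::abort(msg, class = class)
}

dg_warn <- function(msg) {
  rlang::warn(msg, class = "dgnet_warning")
}

# A local RNG scope: runs `expr` under the given seed without disturbing the
# caller's RNG state. All stochastic operations take an explicit seed and
# route through this helper; the package never touches the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
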