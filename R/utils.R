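#' @importFrom methods new is slot validObject setValidity show
#' @importFrom stats runif setNames
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# All stochastic steps in the package route through this so that a seed given
# to an exported function fully determines its output.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# round() in R rounds half to even; tabulated percentages use half-up.
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compose a subfamily key
#'
#' Subfamilies are identified throughout the package by strings of the form
#' `"KS_a"`: the type II PKS class and the subfamily letter joined by an
#' underscore.
#'
#' @param pksClass Character vector of class names (e.g. `"KS"`, `"CYC"`).
#' @param subfamily Character vector of subfamily letters (`"a"`–`"f"`).
#' @return Character vector of keys.
#' @examples
#' subfamilyKey("ARO", c("a", "b"))
#' @export
subfamilyKey <- function(pksClass, subfamily) {
  paste(pksClass, subfamily, sep = "_")
}

splitSubfamilyKey <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  data.frame(
    pks_class = vapply(parts, `[`, "", 1L),
    subfamily = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

# The eleven type II PKS classes.
PKS_CLASSES <- c("KS", "CLF", "ACP", "KR", "ARO", "CYC",
                 "KSIII", "AL", "AT", "MCAT", "TE")

# Aromatic polyketide chemotype codes used in tables and predictions.
CHEMOTYPE_CODES <- c(
  Ang      = "Angucyclines",
  Ant      = "Anthracyclines",
  Ben      = "Benzoisochromanequinones",
  Pen      = "Pentangular polyphenols",
  Tcm      = "Tetracenomycins",
  `Tet/Aur` = "Tetracyclines/aureolic acids"
)

UNCLASSIFIED <- "Unc"

# Standard 20-letter amino-acid alphabet; X is tolerated as an ambiguity code.
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

checkTool <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop("external tool '", tool, "' not found on the PATH", call. = FALSE)
  }
  unname(path)
}
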