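#' @importFrom stats density fisher.test kmeans p.adjust pnorm quantile rbinom
#'   rgamma rnorm runif sd setNames wilcox.test cor phyper dbinom
#' @importFrom utils read.table write.table head
NULL

#' Canonical site key
#'
#' Sites are keyed throughout the package as `"chrom:pos:strand"`, with `pos`
#' the 0-based coordinate of the methylated adenosine.
#'
#' @param chrom,pos,strand vectors of equal length (or length 1, recycled).
#' @return character vector of keys.
#' @export
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

#' Split site keys back into their components
#'
#' @param keys character vector of `"chrom:pos:strand"` keys.
#' @return data.frame with columns `chrom`, `pos` (integer) and `strand`.
#' @export
parse_site_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed site key: ", keys[which(bad)[1L]])
  data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    strand = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# internal: assert a scalar probability
check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must be a probability in [0, 1]")
  }
  invisible(x)
}

# internal: assert a non-degenerate (min, max) integer range
check_range <- function(x, what) {
  if (length(x) != 2L || any(is.na(x)) || x[1L] > x[2L] || x[1L] < 1) {
    stop(what, " must be a (min, max) range with 1 <= min <= max")
  }
  invisible(as.integer(x))
}

# internal: sample() without the length-1 surprise
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
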