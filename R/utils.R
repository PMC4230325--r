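#' @importFrom methods new validObject is slot
#' @importFrom stats as.dist cor cutree dist dpois hclust median medpolish
#'   p.adjust phyper prcomp quantile rbinom rlnorm rnorm rpois runif sd
#'   setNames uniroot var
#' @importFrom utils head read.delim write.table
NULL

#' Emit a timestamped log line to standard error
#'
#' Logging is controlled by \code{options(CTCscope.log.level = ...)} with
#' levels \code{"debug" < "info" < "warn"}; the default level is
#' \code{"info"}.
#'
#' @param msg character message (sprintf-style with \code{...}).
#' @param ... values interpolated into \code{msg}.
#' @param level one of \code{"debug"}, \code{"info"}, \code{"warn"}.
#' @return invisibly, the formatted line.
#' @export
ctcLog <- function(msg, ..., level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  shown <- getOption("CTCscope.log.level", "info")
  line <- sprintf("[%s] %-5s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), sprintf(msg, ...))
  if (levels[[level]] >= levels[[shown]]) message(line)
  invisible(line)
}

#' Derive a named substream seed from a root seed
#'
#' Every stochastic stage of the pipeline draws its seed from the root seed
#' through a named substream, so that stages are individually reproducible
#' and adding a stage never perturbs the draws of another.
#'
#' @param seed non-negative integer root seed.
#' @param name character substream name.
#' @return an integer seed below 2^31.
#' @export
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

# strict %in% with informative error for missing genes
.matchGenes <- function(genes, universe, what = "gene") {
  miss <- setdiff(genes, universe)
  if (length(miss))
    stop(sprintf("unknown %s id(s): %s", what,
                 paste(head(miss, 5L), collapse = ", ")), call. = FALSE)
  match(genes, universe)
}
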