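`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_inputmap <- function(msg, class) {
  stop(structure(
    class = c(class, "inputmap_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Population (ddof = 0) standard deviation; the Z-score convention used
# throughout the package.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
with_fixed_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Auto-detect comma vs tab delimiter from the header line.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.table(path, sep = sniff_delim(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

as_values_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && !is.null(x$values)) return(x$values)
  stop("cannot extract a values matrix from object of class ",
       paste(class(x), collapse = "/"))
}
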