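#' @importFrom rlang abort warn %||%
#' @importFrom stats setNames
NULL

# binary row index: first label is the most significant bit, so the index
# enumerates parent-state bitstrings "00","01","10","11",... in order
bit_index <- function(states) {
  k <- ncol(states)
  as.integer(as.matrix(states) %*% (2^((k - 1):0))) + 1L
}

bitstrings <- function(k) {
  if (k == 0L) return("")
  grid <- expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE]
  apply(grid, 1L, paste0, collapse = "")
}

logit <- function(p) log(p) - log1p(-p)

plogis_ <- function(x) 1 / (1 + exp(-x))

# Shannon entropy (bits) of a probability vector; 0 log 0 = 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# rowwise entropy (bits) of a matrix of counts, one distribution per row
row_entropy_counts <- function(counts) {
  n <- rowSums(counts)
  p <- counts / n
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

# deterministic 31-bit hash of a character vector, for derived seeds
label_hash <- function(labels, base_seed = 0L) {
  x <- utf8ToInt(paste(sort(labels), collapse = "\r"))
  h <- 0
  for (v in x) h <- (h * 31 + v) %% 268435456  # 2^28
  as.integer((h + base_seed %% 268435456) %% 268435456)
}

check_binary_data <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of 0/1 values.", call = call)
  }
  if (anyDuplicated(names(data))) {
    abort("column labels must be unique.", call = call)
  }
  if (nrow(data) < 1L) abort("`data` must have at least one row.", call = call)
  for (nm in names(data)) {
    v <- data[[nm]]
    if (anyNA(v)) {
      abort(paste0("column `", nm, "` contains missing values; ",
                   "remove or impute them before analysis."), call = call)
    }
    if (!all(v %in% c(0, 1))) {
      abort(paste0("column `", nm, "` contains values other than 0/1."),
            call = call)
    }
  }
  invisible(data)
}

check_labels_present <- function(data, labels, call = rlang::caller_env()) {
  missing <- setdiff(labels, names(data))
  if (length(missing)) {
    abort(paste0("unknown variable label(s): ", paste(missing, collapse = ", ")),
          call = call)
  }
  invisible(labels)
}
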