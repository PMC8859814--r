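# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 1.5 -> 2 and -1.5 -> -2), unlike [base::round()], which rounds
#' half to even. Used to discretise -log10(q) significance levels.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of rounded values.
#' @export
round_half_away <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# stop() with a class so callers can distinguish configuration errors
# from stage failures programmatically.
cb_stop <- function(..., class = "chicbench_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Checked TSV reader: no header by default (rmap/baitmap convention).
read_tsv_plain <- function(path, col_names, header = FALSE,
                           colClasses = NA) {
  if (!file.exists(path)) {
    cb_stop("file not found: ", path, class = "chicbench_config_error")
  }
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE, colClasses = colClasses,
                          quote = "", comment.char = "")
  if (!header) {
    if (ncol(df) != length(col_names)) {
      cb_stop(path, ": expected ", length(col_names), " columns, found ",
              ncol(df))
    }
    names(df) <- col_names
  }
  df
}

write_tsv_plain <- function(df, path, header = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
}

# %in%-style set membership for pair keys
pair_key <- function(i, j) paste(i, j, sep = "|")
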