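#' Diagnosis block tables
#'
#' A block table partitions the level-3 ICD-10 code space into contiguous,
#' disjoint code ranges ("blocks"). The WHO defines 131 such blocks for the
#' chapters A00--N99; a copy ships with the package and is the default used
#' throughout. Smaller synthetic tables can be built for toy examples.
#'
#' @name block_table
NULL

# numeric order of a level-3 code: "A00" -> 0, "B07" -> 107, "N99" -> 1399
code_index <- function(code) {
  ok <- grepl("^[A-Z][0-9]{2}", code)
  if (any(!ok))
    data_error("malformed ICD-10 code(s): ",
               paste(head(code[!ok], 5L), collapse = ", "))
  (match(substr(code, 1L, 1L), LETTERS) - 1L) * 100L +
    as.integer(substr(code, 2L, 3L))
}

code_from_index <- function(idx) {
  paste0(LETTERS[idx %/% 100L + 1L], sprintf("%02d", idx %% 100L))
}

validate_block_table <- function(bt, source = "block table") {
  need <- c("block_id", "first_code", "last_code")
  if (!all(need %in% names(bt)))
    data_error(source, ": missing column(s) ",
               paste(setdiff(need, names(bt)), collapse = ", "))
  lo <- code_index(bt$first_code)
  hi <- code_index(bt$last_code)
  bad <- which(hi < lo)
  if (length(bad))
    data_error(source, ": range end before start at line ", bad[1L] + 1L,
               " (", bt$first_code[bad[1L]], "-", bt$last_code[bad[1L]], ")")
  o <- order(lo)
  overlap <- which(lo[o][-1L] <= hi[o][-length(o)])
  if (length(overlap)) {
    row <- o[overlap[1L] + 1L]
    data_error(source, ": overlapping code ranges at line ", row + 1L,
               " (block ", bt$block_id[row], ")")
  }
  invisible(bt)
}

#' Read a diagnosis block table from CSV
#'
#' Expected columns: `block_id,chapter,first_code,last_code,label`. Ranges
#' must be valid and pairwise disjoint; violations raise a parse error that
#' names the offending line.
#'
#' @param path path to a CSV file.
#' @return A `data.table` of class `block_table`, ordered by code range.
#' @export
read_block_table <- function(path) {
  if (!file.exists(path)) config_error("block table file not found: ", path)
  bt <- data.table::fread(path, colClasses = list(character = c("first_code", "last_code")))
  validate_block_table(bt, source = path)
  data.table::setorderv(bt, "first_code")
  bt[, block_id := as.integer(block_id)]
  data.table::setattr(bt, "class", c("block_table", class(bt)))
  bt[]
}

#' Default diagnosis block table
#'
#' With `n_blocks = 131` (the WHO count for A00--N99) the packaged WHO block
#' definitions are loaded verbatim. Any other count yields a synthetic table
#' of `n_blocks` disjoint, contiguous ranges that evenly tile the code space
#' A00--N99 -- useful for small worked examples.
#'
#' @param n_blocks number of blocks (default 131).
#' @param file optional path to a block CSV loaded instead of the default.
#' @return A `data.table` of class `block_table`.
#' @export
default_block_table <- function(n_blocks = 131L, file = NULL) {
  if (!is.null(file)) return(read_block_table(file))
  n_blocks <- assert_count(n_blocks, "n_blocks")
  if (n_blocks == 131L) {
    return(read_block_table(
      system.file("extdata", "icd10_blocks_a00_n99.csv", package = "mmtraj",
                  mustWork = TRUE)))
  }
  # evenly split A00..N99 (14 letters x 100 codes) into n_blocks ranges
  total <- 14L * 100L
  if (n_blocks > total) config_error("n_blocks must be <= ", total)
  cuts <- floor(seq(0L, total, length.out = n_blocks + 1L))
  bt <- data.table::data.table(
    block_id = seq_len(n_blocks) - 1L,
    chapter = "synthetic",
    first_code = code_from_index(cuts[-length(cuts)]),
    last_code = code_from_index(cuts[-1L] - 1L),
    label = paste0("synthetic block ", seq_len(n_blocks) - 1L)
  )
  validate_block_table(bt)
  data.table::setattr(bt, "class", c("block_table", class(bt)))
  bt[]
}

#' Map level-3 ICD-10 codes to diagnosis blocks
#'
#' Codes with more than three characters are truncated to level 3 before
#' lookup. Codes outside every range of the table (for example chapter O--Z
#' codes against an A00--N99 table) map to `NA`.
#'
#' @param code character vector of ICD-10 codes (level 3 or finer).
#' @param blocks a `block_table`.
#' @return Integer vector of `block_id`s, `NA` where the code is unmapped.
#' @export
map_code_to_block <- function(code, blocks) {
  code3 <- substr(code, 1L, 3L)
  idx <- code_index(code3)
  lo <- code_index(blocks$first_code)
  hi <- code_index(blocks$last_code)
  o <- order(lo)
  pos <- findInterval(idx, lo[o])
  out <- rep(NA_integer_, length(idx))
  hit <- pos >= 1L
  hit[hit] <- idx[hit] <= hi[o][pos[hit]]
  out[hit] <- blocks$block_id[o][pos[hit]]
  out
}

# is the (level-3 truncated) code inside [first, last]? vectorised
code_in_range <- function(code, first = "A00", last = "N99") {
  idx <- code_index(substr(code, 1L, 3L))
  idx >= code_index(first) & idx <= code_index(last)
}

# draw one random level-3 code inside block b of `blocks` (vectorised over b)
sample_code_in_block <- function(block_id, blocks) {
  row <- match(block_id, blocks$block_id)
  lo <- code_index(blocks$first_code[row])
  hi <- code_index(blocks$last_code[row])
  code_from_index(lo + floor(runif(length(block_id)) * (hi - lo + 1L)))
}
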