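# Symbology tables: Code 128 and UPC-A.
#
# Code 128 symbols are stored as 6-digit run-width strings (bar, space,
# bar, space, bar, space), 11 modules per symbol; index i holds symbol
# value i - 1 (0..106). The stop pattern has a seventh, closing bar run.
# Structural invariants (6 runs, width sum 11, even bar parity) are
# asserted in the test suite.

CODE128_PATTERNS <- c(
  "212222", "222122", "222221", "121223", "121322", "131222", "122213",
  "122312", "132212", "221213", "221312", "231212", "112232", "122132",
  "122231", "113222", "123122", "123221", "223211", "221132", "221231",
  "213212", "223112", "312131", "311222", "321122", "321221", "312212",
  "322112", "322211", "212123", "212321", "232121", "111323", "131123",
  "131321", "112313", "132113", "132311", "211313", "231113", "231311",
  "112133", "112331", "132131", "113123", "113321", "133121", "313121",
  "211331", "231131", "213113", "213311", "213131", "311123", "311321",
  "331121", "312113", "312311", "332111", "314111", "221411", "431111",
  "111224", "111422", "121124", "121421", "141122", "141221", "112214",
  "112412", "122114", "122411", "142112", "142211", "241211", "221114",
  "413111", "241112", "134111", "111242", "121142", "121241", "114212",
  "124112", "124211", "411212", "421112", "421211", "212141", "214121",
  "412121", "111143", "111341", "131141", "114113", "114311", "411113",
  "411311", "113141", "114131", "311141", "411131", "211412", "211214",
  "211232"
)
CODE128_STOP <- "2331112"

C128_START_A <- 103L; C128_START_B <- 104L; C128_START_C <- 105L
C128_CODE_C <- 99L; C128_CODE_B <- 100L; C128_CODE_A <- 101L
C128_SHIFT <- 98L

pattern_to_widths <- function(p) as.integer(strsplit(p, "")[[1]])

# value -> character for code sets A and B (specials return NA)
c128_value_to_char <- function(value, set) {
  if (set == "B") {
    if (value <= 94) return(rawToChar(as.raw(value + 32L)))
    return(NA_character_)
  }
  if (set == "A") {
    if (value <= 63) return(rawToChar(as.raw(value + 32L)))
    if (value <= 95) return(rawToChar(as.raw(value - 64L)))
    return(NA_character_)
  }
  stop("bad set")
}

c128_char_to_value <- function(ch) {
  v <- utf8ToInt(ch)
  if (is.na(v) || v < 32 || v > 126) return(NA_integer_)
  v - 32L
}

# UPC-A digit run widths (4 runs per digit, 7 modules); identical for the
# left (space-first) and right (bar-first) halves.
UPCA_RUNS <- matrix(c(
  3, 2, 1, 1,   # 0
  2, 2, 2, 1,   # 1
  2, 1, 2, 2,   # 2
  1, 4, 1, 1,   # 3
  1, 1, 3, 2,   # 4
  1, 2, 3, 1,   # 5
  1, 1, 1, 4,   # 6
  1, 3, 1, 2,   # 7
  1, 2, 1, 3,   # 8
  3, 1, 1, 2    # 9
), ncol = 4, byrow = TRUE)

#' UPC-A check digit
#'
#' Modulo-10 check digit over the first 11 digits, weight 3 on odd
#' (1-indexed) positions and 1 on even.
#'
#' @param digits11 string of 11 digits.
#' @return the check digit, 0..9.
#' @export
upca_check_digit <- function(digits11) {
  d <- as.integer(strsplit(digits11, "")[[1]])
  if (length(d) != 11L || anyNA(d)) stop("expected 11 digits")
  s <- sum(d * rep(c(3L, 1L), length.out = 11L))
  (10L - s %% 10L) %% 10L
}

# Code 128 checksum over a value sequence (start value first, data after)
c128_checksum <- function(values) {
  data <- values[-1]
  as.integer((values[1] + if (length(data)) sum(seq_along(data) * data) else 0L) %% 103L)
}
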