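# Internal bit-stream reader/writer. Bits are stored as integer 0/1 vectors,
# most-significant bit first within every multi-bit field (big-endian), and
# packed to bytes only when a container is written to disk.

.bit_writer <- function(init_capacity = 1024L) {
  buf <- integer(init_capacity)
  n <- 0L

  ensure <- function(extra) {
    while (n + extra > length(buf)) {
      buf[length(buf) * 2L] <<- 0L
    }
  }

  list(
    write_bits = function(value, width) {
      # value is a non-negative number < 2^width (width <= 48)
      stopifnot(width >= 1, value >= 0, value < 2^width)
      ensure(width)
      bits <- floor(value / 2^((width - 1L):0)) %% 2
      buf[(n + 1L):(n + width)] <<- as.integer(bits)
      n <<- n + width
    },
    write_bitvec = function(v) {
      k <- length(v)
      if (k == 0L) return(invisible(NULL))
      ensure(k)
      buf[(n + 1L):(n + k)] <<- as.integer(v)
      n <<- n + k
    },
    bits = function() buf[seq_len(n)],
    length = function() n
  )
}

.bit_reader <- function(bits) {
  pos <- 1L
  n <- length(bits)

  list(
    read_bits = function(width) {
      if (pos + width - 1L > n) {
        stop("malformed container: bit stream truncated", call. = FALSE)
      }
      v <- bits[pos:(pos + width - 1L)]
      pos <<- pos + width
      sum(v * 2^((width - 1L):0))
    },
    read_bitvec = function(k) {
      if (k == 0L) return(integer(0))
      if (pos + k - 1L > n) {
        stop("malformed container: bit stream truncated", call. = FALSE)
      }
      v <- bits[pos:(pos + k - 1L)]
      pos <<- pos + k
      v
    },
    skip = function(k) {
      pos <<- pos + as.integer(k)
    },
    position = function() pos,
    remaining = function() n - pos + 1L
  )
}

# Pack a 0/1 integer vector into raw bytes, MSB-first; pad with zeros.
.bits_to_raw <- function(bits) {
  pad <- (-length(bits)) %% 8L
  if (pad > 0L) bits <- c(bits, integer(pad))
  if (length(bits) == 0L) return(raw(0))
  m <- matrix(as.raw(bits), nrow = 8L)
  packBits(as.vector(m[8L:1L, , drop = FALSE]), type = "raw")
}

# Unpack raw bytes into a 0/1 integer vector, MSB-first.
.raw_to_bits <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0))
  b <- as.integer(rawToBits(bytes)) # LSB-first per byte
  m <- matrix(b, nrow = 8L)
  as.vector(m[8L:1L, , drop = FALSE])
}
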