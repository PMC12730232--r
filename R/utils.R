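# 32-bit FNV-1a hash of a string, returned as a double in [0, 2^32).
# bitwXor only takes 31-bit integers, so the byte xor is done on the low
# 8 bits explicitly.
fnv_hash <- function(txt) {
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), as.integer(ch))
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# hex rendering of a 32-bit hash value stored as a double
fnv_hex <- function(h) {
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
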