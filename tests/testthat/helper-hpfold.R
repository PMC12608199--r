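# shared helpers: the two worked-example sequences, a random SAW sampler,
# and a per-session cache so expensive 16-mer pipelines are computed once

SEQ_A <- "HPPHPPPHPHPPHPHP"   # fast folder, E0 = -91
SEQ_B <- "HHHHPHHPHPHPHPHP"   # slow folder, E0 = -103
SEQ_1 <- "PHPPPPHPPHPHPPPP"   # reference sequence no. 1, E0 = -72

.hpfold_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .hpfold_cache))
    assign(key, expr, envir = .hpfold_cache)
  get(key, envir = .hpfold_cache)
}

cached_pipeline <- function(seq_string) {
  cached(paste0("pipeline_", seq_string), run_pipeline(seq_string))
}

# rejection-sampled random self-avoiding walk with n beads
random_saw <- function(n, max_tries = 1000) {
  steps <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  for (try in seq_len(max_tries)) {
    coords <- matrix(0L, n, 3)
    occupied <- "0,0,0"
    ok <- TRUE
    for (k in 2:n) {
      cand <- sample(6)
      placed <- FALSE
      for (d in cand) {
        nxt <- coords[k - 1, ] + steps[d, ]
        key <- paste(nxt, collapse = ",")
        if (!key %in% occupied) {
          coords[k, ] <- nxt
          occupied <- c(occupied, key)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(hp_conformation(coords))
  }
  stop("failed to sample a self-avoiding walk")
}

random_hp_string <- function(n) paste(sample(c("H", "P"), n, replace = TRUE),
                                      collapse = "")

dos_as_map <- function(dos) setNames(dos$count, dos$energy)
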