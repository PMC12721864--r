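## Thin R interface over the DPLL kernel in src/sat.cpp.
## Clauses are lists of non-empty integer vectors in DIMACS convention:
## literal +v means variable v true, -v means v false.

flatten_clauses <- function(clauses) {
  lens <- lengths(clauses)
  if (any(lens == 0L)) stop("empty clause", call. = FALSE)
  list(lits = as.integer(unlist(clauses, use.names = FALSE)),
       lens = as.integer(lens))
}

sat_solve <- function(n_vars, clauses, seed = 1L, assumptions = integer(0),
                      max_conflicts = 0) {
  f <- flatten_clauses(clauses)
  cpp_sat_solve(as.integer(n_vars), f$lits, f$lens,
                as.integer(seed), as.integer(assumptions),
                as.double(max_conflicts))
}

sat_enumerate <- function(n_vars, clauses, seed = 1L, max_models = 500L,
                          block_vars = seq_len(n_vars),
                          assumptions = integer(0)) {
  f <- flatten_clauses(clauses)
  cpp_sat_enumerate(as.integer(n_vars), f$lits, f$lens, as.integer(seed),
                    as.integer(max_models), as.integer(block_vars),
                    as.integer(assumptions))
}

# independent clause-by-clause check that a 0/1 assignment satisfies a CNF
sat_check_model <- function(assignment, clauses) {
  all(vapply(clauses, function(cl) {
    v <- abs(cl)
    any((cl > 0L & assignment[v] == 1L) | (cl < 0L & assignment[v] == 0L))
  }, TRUE))
}
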