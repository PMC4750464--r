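# Independent oracles used across the suite. These deliberately avoid the
# package's simulation/KS code paths: trajectories are iterated in plain R
# from the truth tables, and the KS statistic is recomputed from empirical
# CDFs directly.

# exhaustive synchronous trajectory for models without externals (or with
# externally supplied fixed states), starting from a named 0/1 state vector
oracle_trajectory <- function(model, init, steps) {
  ids <- model$components$id
  state <- setNames(integer(length(ids)), ids)
  state[names(init)] <- as.integer(init)
  traj <- matrix(0L, nrow = length(ids), ncol = steps + 1,
                 dimnames = list(ids, NULL))
  traj[, 1] <- state[ids]
  for (t in seq_len(steps)) {
    nxt <- state
    for (target in names(model$functions)) {
      f <- model$functions[[target]]
      bits <- state[f$regulators]
      idx <- sum(bits * 2^(rev(seq_along(bits)) - 1)) + 1
      nxt[target] <- f$outputs[idx]
    }
    state <- nxt
    traj[, t + 1] <- state[ids]
  }
  traj
}

# AL over the trailing window of an oracle trajectory (percent)
oracle_al <- function(traj, window) {
  steps <- ncol(traj) - 1
  idx <- (steps - window + 2):(steps + 1)  # states after steps T-W+1 .. T
  100 * rowMeans(traj[, idx, drop = FALSE])
}

# two-sample KS statistic as max |ECDF difference| over the pooled points
ks_statistic_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(fx - fy))
}

# minimal SBML-qual document for a 3-node model: A = NOT B, B = A,
# external (transition-free) species E
write_sbml_toy <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1"',
    '      level="3" version="1" qual:required="true">',
    '  <model id="toy">',
    '    <qual:listOfQualitativeSpecies>',
    '      <qual:qualitativeSpecies qual:id="A" qual:maxLevel="1" qual:constant="false"/>',
    '      <qual:qualitativeSpecies qual:id="B" qual:maxLevel="1" qual:constant="false"/>',
    '      <qual:qualitativeSpecies qual:id="E" qual:maxLevel="1" qual:constant="false"/>',
    '    </qual:listOfQualitativeSpecies>',
    '    <qual:listOfTransitions>',
    '      <qual:transition qual:id="tr_A">',
    '        <qual:listOfInputs>',
    '          <qual:input qual:qualitativeSpecies="B" qual:transitionEffect="none"/>',
    '        </qual:listOfInputs>',
    '        <qual:listOfOutputs>',
    '          <qual:output qual:qualitativeSpecies="A" qual:transitionEffect="assignmentLevel"/>',
    '        </qual:listOfOutputs>',
    '        <qual:listOfFunctionTerms>',
    '          <qual:defaultTerm qual:resultLevel="0"/>',
    '          <qual:functionTerm qual:resultLevel="1">',
    '            <math xmlns="http://www.w3.org/1998/Math/MathML">',
    '              <apply><not/><apply><eq/><ci>B</ci><cn type="integer">1</cn></apply></apply>',
    '            </math>',
    '          </qual:functionTerm>',
    '        </qual:listOfFunctionTerms>',
    '      </qual:transition>',
    '      <qual:transition qual:id="tr_B">',
    '        <qual:listOfInputs>',
    '          <qual:input qual:qualitativeSpecies="A" qual:transitionEffect="none"/>',
    '        </qual:listOfInputs>',
    '        <qual:listOfOutputs>',
    '          <qual:output qual:qualitativeSpecies="B" qual:transitionEffect="assignmentLevel"/>',
    '        </qual:listOfOutputs>',
    '        <qual:listOfFunctionTerms>',
    '          <qual:defaultTerm qual:resultLevel="0"/>',
    '          <qual:functionTerm qual:resultLevel="1">',
    '            <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>A</ci></math>',
    '          </qual:functionTerm>',
    '        </qual:listOfFunctionTerms>',
    '      </qual:transition>',
    '    </qual:listOfTransitions>',
    '  </model>',
    '</sbml>'
  ), path)
  invisible(path)
}

# single species, no transitions
write_sbml_single <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1"',
    '      level="3" version="1" qual:required="true">',
    '  <model id="one">',
    '    <qual:listOfQualitativeSpecies>',
    '      <qual:qualitativeSpecies qual:id="L" qual:maxLevel="1" qual:constant="false"/>',
    '    </qual:listOfQualitativeSpecies>',
    '  </model>',
    '</sbml>'
  ), path)
  invisible(path)
}

# same topology but a non-Boolean maxLevel, to exercise the unsupported-model error
write_sbml_multilevel <- function(path) {
  txt <- readLines(write_sbml_single(path))
  writeLines(sub('qual:maxLevel="1"', 'qual:maxLevel="2"', txt), path)
  invisible(path)
}

# equality of models up to display names
expect_models_equal <- function(a, b) {
  expect_equal(a$components[, c("id", "kind")], b$components[, c("id", "kind")])
  expect_equal(a$functions, b$functions)
}
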