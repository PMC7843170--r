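---
title: "Exact MLCS search with dominant points: model, design and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact MLCS search with dominant points: model, design and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpmlcs)
```

## The problem

Given $n \ge 2$ sequences over a common alphabet, a *common subsequence* is a
string obtainable from every sequence by deleting residues (order preserved,
contiguity not required).  The **multiple longest common subsequence** (MLCS)
problem asks for *all* the longest such strings.  For DNA and protein
sequences the MLCS preserves the residues conserved across all inputs, which
is why it underlies similarity scoring, conserved-segment detection and
alignment seeding.  The problem is NP-hard in $n$; exact algorithms are
nonetheless the tool of choice when the solution itself (not an
approximation) is needed, and the dominant-point family is the standard exact
approach.

## The dominant-point model

Index each sequence from 1; position 0 is a virtual "before start"
coordinate.  A *point* $P = [p_1, \dots, p_n]$ picks one position in each
sequence.  $P$ is a **match point** when all sequences carry the same symbol
at their respective positions.  For two points, $P$ **dominates** $Q$ when
$p_j \le q_j$ for all $j$, and **strongly dominates** $Q$ when $p_j < q_j$
for all $j$ (`dominates()` reports both verdicts).  A match point reachable
in $k$ successor steps from the all-zero source ends a common subsequence of
length $k$; the classical *k-dominant points* are the level-$k$ match points
not dominated by another level-$k$ point — the level's Pareto frontier.

The search is level-synchronous breadth-first:

1. **Legality check.** Residues are validated against a fixed alphabet
   (`validate_sequences()`); violations are reported as data with sequence
   id, position and symbol.  The check never repairs input: lowercase is
   accepted and uppercased, but `U` in a DNA set or an ambiguity code such
   as `N`/`B` is a violation unless the alphabet is *explicitly* extended
   (`mlcs_alphabet("protein", extra = "B")`, CLI flag `--extend`).  Exact
   symbol equality is what makes a match point a match point, so silent
   repair would change the problem being solved.
2. **Successor tables.** For every sequence, symbol and position, the next
   occurrence of that symbol strictly after the position
   (`build_successor_table()`).  This makes one-step match-point generation
   a table lookup per symbol (`successor_match_points()`).  `NA` is the
   explicit "no successor" sentinel — 0 stays reserved for the virtual
   source coordinate, which avoids the classic off-by-one in this structure.
   Tables are built once and never mutated.
3. **Expansion and pruning.** Each level-$k$ point proposes one candidate
   per symbol; candidates record their generating parents.  Duplicate
   coordinate vectors are merged, with parent sets unioned
   (`prune_minima()`).  Redundant candidates are then deleted by dominance
   (next section).
4. **Graph construction.** Retained points and their parent edges form a
   DAG; after the last non-empty level $L$ is found, points that cannot
   reach level $L$ are trimmed so every source-to-sink path has exactly $L$
   edges.
5. **Backtracking.** A depth-first traversal spells one string per
   source-to-sink path (`backtrack_enumerate()`); the report carries the
   sorted distinct strings, $L$, the distinct-string count and the raw path
   count.

## Why pruning uses strong dominance

The textbook k-dominant definition suggests pruning any point weakly
dominated by a same-level point.  That is correct for computing the *length*
$L$, or one witness string — but it is **wrong for enumerating all MLCS**,
which is this package's contract.  A minimal counterexample:

```{r}
res <- mlcs(c("ABAB", "BAAB"), alphabet = mlcs_alphabet("protein", extra = "B"))
res$strings
```

Both `AAB` and `BAB` are longest (length 3).  The only embedding of the
prefix `AA` ends at point $[3,3]$, which is weakly dominated by $[3,2]$, the
minimal embedding of `BA`.  Weak pruning deletes $[3,3]$ and with it the
string `AAB` — the dominated point spells a *different prefix* than its
dominator, and domination says nothing about the spelled symbols.  Strong
dominance ($<$ in every coordinate) is the right redundancy notion here: if
$Q < P$ in every coordinate, every continuation of $P$ (positions strictly
beyond $P$) is also a continuation of $Q$ **and** the pruned point's own
prefix strings are recovered because any string ending at $P$ also ends at
some retained point (duplicate merging keeps all parent links).  The
package's property tests assert exact string-set equality against an
independent brute-force oracle across hundreds of random instances; with
weak pruning that suite fails (the fault-injection test demonstrates it),
with strong pruning it passes.

## The two prune modes

* **pf** — dominance pruning alone, as above.
* **hf** — additionally discards a candidate at level $k{+}1$ when
  $k + 1 + \mathrm{ub}(P) < \mathrm{lb}$, where $\mathrm{ub}(P)$ is the
  **admissible upper bound** $\sum_c \min_i \#\{$occurrences of $c$ after
  $p_i\}$ (`extension_upper_bound()`, backed by `build_suffix_counts()`)
  and $\mathrm{lb}$ is the length of a greedy common subsequence
  (`greedy_lower_bound()`: repeatedly take the symbol whose successor
  match point minimizes the coordinate sum, ties broken by alphabet
  order).  No common subsequence extending $P$ can beat
  $\mathrm{ub}(P)$ — each extension character consumes one occurrence of
  its symbol in every suffix — so the filter never removes a point on an
  optimal path, and `hf` provably returns exactly the `pf` result.  Its
  value is fewer retained points on instances with a strong greedy bound.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alphabet` | `"auto"` | `dna` (4 symbols) iff all residues are A/C/G/T, else `protein` (20); extensions are explicit |
| `prune` | `"pf"` | pruning mode; `hf` adds the admissible bound filter |
| `node_budget` | `1e6` points | cap on total retained points; exceeding it is a classed resource error naming the level reached, not a crash |
| `enum_budget` | `1e6` paths | cap on backtracking work; the DAG can hold exponentially many paths |
| `seed` | — | the synthetic generator is a pure function of `(n, length, alphabet, seed)` |

Budgets exist because the level sets (and the number of longest paths) grow
exponentially in the worst case; the defaults are comfortable for the
desk-scale instances the package targets (a few sequences of a few hundred
residues) while turning adversarial blow-ups into clean, catchable errors.

## What the synthetic generator emulates — and what it does not

`generate_random_sequences()` draws residues i.i.d. uniform over the
alphabet.  That matches the *combinatorial* structure the algorithm cares
about (symbol positions and repeats) and makes every test reproducible from
a seed without external data.  It does **not** emulate biased base
composition, CpG/codon structure, long repeats, indel-correlated homology
between the sequences, or length heterogeneity beyond what the caller
requests.  Consequently a green test suite certifies algorithmic
correctness — the enumerated set equals the true MLCS set on the tested
distribution and on every adversarial case in the suite — but says nothing
about runtime on real genomic inputs, where similarity between sequences
(not length alone) drives the size of the dominant-point frontier.

## Verification strategy and problem sizes

Correctness claims are anchored to oracles that share no code with the
engine:

* `brute_force_mlcs()` fills the full $(\ell_1{+}1) \times \dots \times
  (\ell_n{+}1)$ scoring lattice (no successor tables, no pruning) and
  backtracks over rightmost symbol occurrences;
* `dp_enumerate_all_lcs()` is the independent two-sequence enumerator over
  the classic DP matrix;
* `verify_result()` re-checks every reported string with a plain two-pointer
  subsequence scan;
* `count_paths()` recounts longest paths by per-node memoization, checked
  against the DFS path count.

The shipped verification sweep uses 204 random instances with $n \in
\{2,3,4\}$, lengths 4–12, both alphabets (the lattice oracle is exponential,
so oracle-checked instances stay small), plus 200 random pairs with lengths
up to 200 for the length-only three-way agreement between full-matrix DP,
two-row DP and the dominant-point search.  These sizes keep the whole suite
in the tens of seconds on one core while covering every code path;
`selftest()` packages a smaller version of the same sweep for end users.

## Numerical and degenerate-input choices

* Positions are 1-based; the all-zero source is the only level-0 point.
* Report strings are sorted with radix (byte) order, so output files are
  byte-identical across runs, platforms and locales; DFS children are
  visited in lexicographic (symbol, positions) order for the same reason.
* $L = 0$ (no shared symbol) yields an empty report: zero strings,
  `length: 0`, `count: 0` — not an error.
* Identical sequences produce the single-chain graph and the sequence
  itself as the unique MLCS.
* Distinct paths can spell identical strings; the headline count is the
  *distinct-string* count (what a user sees in the output), with the raw
  path count reported alongside.
* Equal-coordinate duplicates are merged rather than pruned against each
  other — self-domination must not delete a point.

## Known limitations

* Worst-case time and space remain exponential in $n$; the engine is for
  exact desk-scale analysis, not genome-scale screening.
* No approximate (heuristic-search) modes: every path returns the exact,
  complete MLCS set or a classed resource error.
* The two-row DP mode computes lengths only; linear-space *reconstruction*
  (divide-and-conquer) is out of scope, as are gapped alignments, FASTQ
  input and weighted/constrained LCS variants.
* `dp2` is restricted to $n = 2$ by construction; the registry rejects the
  configuration otherwise.
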