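# dpmlcs — exact enumeration of all multiple longest common subsequences

`dpmlcs` finds **all** longest common subsequences (MLCS) shared by two or
more DNA or protein sequences, exactly. The MLCS of a sequence set collects
the residues conserved across every input in order (not necessarily
contiguously), which makes it a basic primitive for conserved-segment
analysis, similarity scoring and alignment seeding. The package is aimed at
bioinformaticians and algorithm developers who need the *complete, provably
exact* solution set at desk scale — not a single witness string and not an
approximation.

## The algorithm

The engine is the dominant-point method. For sequences
$a_1, \dots, a_n$, a point $P=[p_1,\dots,p_n]$ (1-based positions; the
all-zero point is a virtual source) is a *match point* when
$a_1[p_1] = \dots = a_n[p_n]$. $P$ *dominates* $Q$ when $p_j \le q_j$ for
all $j$, *strongly* when $p_j < q_j$ for all $j$. The search proceeds level
by level:

1. **legality check** of residues against a fixed alphabet (violations are
   data, not repairs);
2. **successor tables** — per sequence, symbol and position, the next
   occurrence of the symbol — make match-point generation O(1) per symbol;
3. **expansion + pruning** — each level-$k$ point proposes one candidate per
   symbol; duplicates are merged (parent sets unioned) and candidates
   strongly dominated by another candidate are deleted. An optional
   heuristic mode (`hf`) also discards candidates whose admissible
   suffix-count upper bound cannot reach a greedy lower bound — provably
   without changing the result;
4. **DAG construction** over the retained points (parent edges, dead ends
   trimmed), in which every source-to-sink path has exactly $L$ edges;
5. **depth-first backtracking** spells every path into a string and reports
   the sorted distinct MLCS set, the length $L$, the distinct count and the
   raw path count.

Pruning uses *strong* dominance deliberately: weak-dominance pruning is
sound for the length but provably loses solution strings when enumerating
the full set (try `mlcs(c("ABAB", "BAAB"), alphabet =
mlcs_alphabet("protein", extra = "B"))` — the weakly pruned search would
miss `AAB`). The package vignette walks through the counterexample.

Also included, behind the same report interface: pairwise DP baselines
(`dp_lcs_length()`, full matrix; `space_opt_lcs_length()`, two rows), an
independent pairwise all-LCS enumerator (`dp_enumerate_all_lcs()`), and an
exponential full-lattice brute-force oracle (`brute_force_mlcs()`) used as
ground truth by the test-suite and `selftest()`.

## Worked example

The classic pair `ABCBDAB` / `BDCABA` (`B` is not a standard amino-acid
code, so the alphabet is extended explicitly):

```r
library(dpmlcs)
ab  <- mlcs_alphabet("protein", extra = "B")
res <- mlcs(c("ABCBDAB", "BDCABA"), alphabet = ab, keep_graph = TRUE)
res
#> Multiple longest common subsequence result
#>   algorithm: dominant/pf
#>   MLCS length: 4
#>   distinct MLCS: 3
#>   BCAB
#>   BCBA
#>   BDAB
```

The two sequences share no common subsequence longer than 4, and exactly
three distinct strings reach that length. The per-level search statistics
show the pruning at work (candidates generated vs. points retained per
level):

```r
res$stats
#>   level candidates retained
#> 1     0         NA        1
#> 2     1          4        2
#> 3     2          6        3
#> 4     3          5        2
#> 5     4          2        2
```

The same result comes out of every other algorithm path
(`algorithm = "dp2"`, `"brute"`, or `prune = "hf"`), and
`verify_result(res, ...)` re-checks each string independently.

A command-line front end is installed with the package
(`system.file("scripts", "mlcs", package = "dpmlcs")`):

```sh
mlcs search input.fasta --algorithm dominant --prune pf --alphabet auto --out report.txt
mlcs generate --n 3 --length 50 --alphabet dna --seed 7 --out random.fasta
mlcs selftest --seed 1 --trials 25
```

Exit codes distinguish input (2), configuration (3), graph-integrity (4)
and resource-budget (5) failures.

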