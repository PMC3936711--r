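"""Reference Markov clustering used as an independent oracle in the tests.

Reads {"graphs": [{"n": int, "edges": [[i, j, w], ...]}, ...], "inflation": x}
as JSON from argv[1]; writes a JSON list of partitions (each a list of
clusters, each a sorted list of 0-based node ids) to argv[2].
"""
import json
import sys

import numpy as np


def mcl_partition(n, edges, inflation, prune=1e-5, tol=1e-8, max_iter=100):
    A = np.zeros((n, n))
    for i, j, w in edges:
        A[int(i), int(j)] = w
        A[int(j), int(i)] = w
    self_loop = A.max(axis=1)
    self_loop[self_loop == 0] = 1.0
    np.fill_diagonal(A, self_loop)
    M = A / A.sum(axis=0, keepdims=True)
    for _ in range(max_iter):
        M2 = np.power(M @ M, inflation)
        M2[M2 < prune] = 0.0
        s = M2.sum(axis=0, keepdims=True)
        s[s == 0] = 1.0
        M2 = M2 / s
        delta = np.abs(M2 - M).max()
        M = M2
        if delta < tol:
            break
    B = (M > 0) | (M.T > 0)
    # connected components of the limit's non-zero structure
    parent = list(range(n))

    def find(x):
        while parent[x] != x:
            parent[x] = parent[parent[x]]
            x = parent[x]
        return x

    for i in range(n):
        for j in range(n):
            if B[i, j]:
                parent[find(i)] = find(j)
    groups = {}
    for i in range(n):
        groups.setdefault(find(i), []).append(i)
    return sorted([sorted(g) for g in groups.values()])


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    out = [mcl_partition(g["n"], g.get("edges", []), payload["inflation"])
           for g in payload["graphs"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
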