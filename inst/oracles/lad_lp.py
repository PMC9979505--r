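"""Least-absolute-deviations regression as a linear program.

Reads {"X": [[...]], "y": [...]} on stdin, solves
    min (1/n) sum_i |y_i - b0 - x_i' b|
exactly with scipy's HiGHS LP solver, and prints the optimum as JSON.
Used as an independent oracle by the test suite.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

d = json.load(sys.stdin)
X = np.asarray(d["X"], dtype=float)
if X.ndim == 1:
    X = X.reshape(-1, 1)
y = np.asarray(d["y"], dtype=float)
n = y.shape[0]
X = X.reshape(n, -1)
q = X.shape[1] + 1
Xa = np.hstack([np.ones((n, 1)), X])

# variables: theta (free, q), u (n, >= 0); min sum u  s.t.  u >= +-(y - Xa theta)
c = np.concatenate([np.zeros(q), np.ones(n)])
A_ub = np.vstack([np.hstack([-Xa, -np.eye(n)]), np.hstack([Xa, -np.eye(n)])])
b_ub = np.concatenate([-y, y])
bounds = [(None, None)] * q + [(0, None)] * n
res = linprog(c, A_ub=A_ub, b_ub=b_ub, bounds=bounds, method="highs")
json.dump({"obj": res.fun / n, "theta": list(res.x[:q]), "status": int(res.status)},
          sys.stdout)
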