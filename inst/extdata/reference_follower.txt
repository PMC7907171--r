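# Hand-written reference wall-follower, expressed as a boolean control
# program under candidate-move interrogation (the expression names the
# direction variable of the move it wants; exactly one direction variable is
# hot when the controller asks about that move).  The rules circulate the
# robot clockwise around any wall it touches (wall to the north -> go east,
# and so on), round convex corners via the diagonal sensors, and default to
# marching north through open space until a wall is met.
If[n&&!e, east,
 If[e&&!s, south,
  If[s&&!w, west,
   If[w&&!n, north,
    If[ne&&!e, east,
     If[se&&!s, south,
      If[sw&&!w, west,
       If[nw&&!n, north,
        If[!n, north, False]]]]]]]]]
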