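# Reference Golgi-to-nucleus S values (Gy per Bq s) for two geometrical
# renderings of the Golgi: polygonal-mesh models (pm) and the simplified
# half-torus CSG representation (csg), listed with Golgi volumes (um^3).
geometry,v_golgi_um3,s_golgi
pm,123,1.05e-04
pm,80,8.71e-05
pm,68,1.05e-04
pm,63,1.32e-04
pm,60,8.57e-05
pm,54,8.12e-05
pm,31,6.96e-05
pm,25,5.41e-05
pm,24,1.22e-04
csg,110,3.67e-05
csg,94,3.70e-05
csg,86,3.75e-05
csg,78,3.60e-05
csg,70,4.40e-05
csg,62,4.78e-05
csg,54,6.32e-05
csg,46,6.71e-05
csg,38,8.87e-05
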