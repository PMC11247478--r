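{"name":"molecule_A","formula":"C19H30O3","atoms":[[1,"C"],[2,"C"],[3,"C"],[4,"C"],[5,"C"],[6,"C"],[7,"O"],[8,"H"],[9,"C"],[10,"C"],[11,"C"],[12,"C"],[13,"C"],[14,"C"],[15,"C"],[16,"C"],[17,"C"],[18,"C"],[19,"C"],[20,"O"],[21,"O"],[22,"C"],[23,"C"],[24,"H"],[25,"H"],[26,"H"],[27,"H"],[28,"H"],[29,"H"],[30,"H"],[31,"H"],[32,"H"],[33,"H"],[34,"H"],[35,"H"],[36,"H"],[37,"H"],[38,"H"],[39,"H"],[40,"H"],[41,"H"],[42,"H"],[43,"H"],[44,"H"],[45,"H"],[46,"H"],[47,"H"],[48,"H"],[49,"H"],[50,"H"],[51,"H"],[52,"H"]],"bonds":[[1,2,2,null],[2,3,1,null],[3,4,2,null],[4,5,1,null],[5,6,2,null],[6,1,1,null],[4,7,1,null],[7,8,1,"1A"],[3,9,1,null],[9,10,1,null],[9,11,1,null],[9,12,1,null],[5,13,1,null],[13,14,1,null],[13,15,1,null],[13,16,1,null],[1,17,1,null],[17,18,1,null],[18,19,1,"2A"],[19,20,2,null],[19,21,1,"3A"],[21,22,1,"4A"],[22,23,1,null],[2,24,1,null],[6,25,1,null],[10,26,1,null],[10,27,1,null],[10,28,1,null],[11,29,1,null],[11,30,1,null],[11,31,1,null],[12,32,1,null],[12,33,1,null],[12,34,1,null],[14,35,1,null],[14,36,1,null],[14,37,1,null],[15,38,1,null],[15,39,1,null],[15,40,1,null],[16,41,1,null],[16,42,1,null],[16,43,1,null],[17,44,1,null],[17,45,1,null],[18,46,1,null],[18,47,1,null],[22,48,1,null],[22,49,1,null],[23,50,1,null],[23,51,1,null],[23,52,1,null]]}
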