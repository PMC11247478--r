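{"name":"molecule_B","formula":"C26H34O4","atoms":[[1,"C"],[2,"C"],[3,"C"],[4,"C"],[5,"C"],[6,"C"],[7,"O"],[8,"H"],[9,"C"],[10,"C"],[11,"C"],[12,"C"],[13,"C"],[14,"C"],[15,"C"],[16,"O"],[17,"H"],[18,"H"],[19,"H"],[20,"H"],[21,"H"],[22,"H"],[23,"H"],[24,"H"],[25,"H"],[26,"H"],[27,"H"],[28,"H"],[29,"H"],[30,"H"],[31,"H"],[32,"H"],[33,"C"],[34,"C"],[35,"C"],[36,"C"],[37,"C"],[38,"C"],[39,"O"],[40,"H"],[41,"C"],[42,"C"],[43,"C"],[44,"C"],[45,"C"],[46,"C"],[47,"C"],[48,"O"],[49,"H"],[50,"H"],[51,"H"],[52,"H"],[53,"H"],[54,"H"],[55,"H"],[56,"H"],[57,"H"],[58,"H"],[59,"H"],[60,"H"],[61,"H"],[62,"H"],[63,"H"],[64,"H"]],"bonds":[[1,2,2,null],[2,3,1,null],[3,4,2,null],[4,5,1,null],[5,6,2,null],[6,1,1,null],[2,7,1,"3B"],[7,8,1,"1B"],[3,9,1,null],[9,10,1,null],[9,11,1,null],[9,12,1,null],[5,13,1,null],[13,14,2,null],[14,15,1,null],[15,16,1,"4B"],[16,17,1,"2B"],[4,18,1,null],[6,19,1,null],[10,20,1,null],[10,21,1,null],[10,22,1,null],[11,23,1,null],[11,24,1,null],[11,25,1,null],[12,26,1,null],[12,27,1,null],[12,28,1,null],[13,29,1,null],[14,30,1,null],[15,31,1,null],[15,32,1,null],[33,34,2,null],[34,35,1,null],[35,36,2,null],[36,37,1,null],[37,38,2,null],[38,33,1,null],[34,39,1,"3B'"],[39,40,1,"1B'"],[35,41,1,null],[41,42,1,null],[41,43,1,null],[41,44,1,null],[37,45,1,null],[45,46,2,null],[46,47,1,null],[47,48,1,"4B'"],[48,49,1,"2B'"],[36,50,1,null],[38,51,1,null],[42,52,1,null],[42,53,1,null],[42,54,1,null],[43,55,1,null],[43,56,1,null],[43,57,1,null],[44,58,1,null],[44,59,1,null],[44,60,1,null],[45,61,1,null],[46,62,1,null],[47,63,1,null],[47,64,1,null],[1,33,1,null]]}
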